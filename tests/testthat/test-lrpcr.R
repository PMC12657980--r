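test_that("extract_breakpoint follows the donor/acceptor block definitions", {
  # two-block deletional chain with no gap
  ch <- make_chain(list(c(9000, 12000, 0, 3000, "+"),
                        c(41000, 43000, 3000, 5000, "+")), 5000)
  cl <- extract_breakpoint(ch, toy_locus)
  expect_false(cl$complex)
  expect_equal(cl$donor_break, 12000)
  expect_equal(cl$acceptor_break, 41000)
  expect_equal(cl$orientation, "DEL")
  expect_equal(cl$gap_read_bases, 0)

  # blocks overlapping by 5 read bases: donor-maximal placement advances
  # the acceptor block and records the ambiguity
  ch5 <- make_chain(list(c(9000, 12000, 0, 3000, "+"),
                         c(41000, 43000, 2995, 4995, "+")), 4995)
  cl5 <- extract_breakpoint(ch5, toy_locus)
  expect_equal(cl5$mh_ambiguity, 5)
  expect_equal(cl5$acceptor_break, 41005)
  expect_equal(cl5$donor_break, 12000)

  # positive gap is the untemplated-insertion candidate
  chg <- make_chain(list(c(9000, 12000, 0, 3000, "+"),
                         c(41000, 43000, 3004, 5004, "+")), 5004)
  clg <- extract_breakpoint(chg, toy_locus)
  expect_equal(clg$gap_read_bases, 4)
  expect_equal(clg$ins_len, 4)

  # inversional chain: acceptor block on the opposite strand, break at the
  # junction-proximal (canonical end) boundary
  chi <- make_chain(list(c(9000, 12000, 0, 3000, "+"),
                         c(41000, 43000, 3000, 5000, "-")), 5000)
  cli <- extract_breakpoint(chi, toy_locus)
  expect_equal(cli$orientation, "INV")
  expect_equal(cli$acceptor_break, 43000)

  # three-block chain donor->donor->acceptor: primary junction spans the
  # 5'-end donor block to the acceptor block, one secondary junction
  ch3 <- make_chain(list(c(9000, 10500, 0, 1500, "+"),
                         c(12000, 13000, 1500, 2500, "+"),
                         c(41000, 43000, 2500, 4500, "+")), 4500)
  cl3 <- extract_breakpoint(ch3, toy_locus)
  expect_equal(cl3$donor_break, 10500)
  expect_equal(cl3$acceptor_break, 41000)
  expect_equal(cl3$n_secondary, 1)
  expect_equal(unname(cl3$secondary[[1]]), c(10500, 12000))

  # a reverse-sequenced read is flipped to canonical orientation
  chr <- make_chain(list(c(41000, 43000, 0, 2000, "-"),
                         c(9000, 12000, 2000, 5000, "-")), 5000)
  clr <- extract_breakpoint(chr, toy_locus)
  expect_false(clr$complex)
  expect_equal(clr$donor_break, 12000)
  expect_equal(clr$acceptor_break, 41000)
  expect_equal(clr$orientation, "DEL")

  # > max_blocks chains are flagged complex; failing the ROI precondition
  # is an error
  ch6 <- make_chain(lapply(0:5, function(i)
    c(9000 + 500 * i, 9300 + 500 * i, 700 * i, 700 * i + 300, "+")), 4200)
  ch6$blocks$ref_start[6] <- 41000; ch6$blocks$ref_end[6] <- 41300
  expect_true(extract_breakpoint(ch6, toy_locus)$complex)
  expect_error(extract_breakpoint(
    make_chain(list(c(9000, 12000, 0, 3000, "+")), 3000), toy_locus),
    "ROI")
})

test_that("depth deduplication keeps >= min_depth keys and the blocklist drops keys", {
  mk <- function(d, a, n) data.frame(
    read_id = sprintf("x%d", seq_len(n)), donor_break = d, acceptor_break = a,
    orientation = "DEL", gap_read_bases = 0, ins_len = 0, ins_seq = "",
    mh_ambiguity = 0, amplicon_len = 9000, n_secondary = 0)
  calls <- rbind(mk(12000, 41000, 12), mk(12500, 41500, 10),
                 mk(13000, 42000, 9))
  jx <- dedup_and_filter(calls, min_depth = 10, locus = toy_locus)
  expect_equal(nrow(jx), 2)
  expect_setequal(jx$depth, c(12, 10))
  expect_equal(nrow(dedup_and_filter(calls, min_depth = 11,
                                     locus = toy_locus)), 1)

  # monotonicity: raising min_depth never increases the junction count
  n_at <- vapply(1:20, function(md)
    nrow(dedup_and_filter(calls, min_depth = md, locus = toy_locus)),
    numeric(1))
  expect_true(all(diff(n_at) <= 0))

  # a depth-50 key matching a blocklist pair is removed
  bl_locus <- toy_locus
  bl_locus$blocklist <- data.frame(donor_break = 12000,
                                   acceptor_break = 41000)
  calls2 <- rbind(mk(12000, 41000, 50), mk(12500, 41500, 10))
  jx2 <- dedup_and_filter(calls2, min_depth = 10, locus = bl_locus)
  expect_equal(nrow(jx2), 1)
  expect_equal(jx2$donor_break, 12500)

  expect_equal(nrow(dedup_and_filter(mk(1, 2, 3)[0, ], locus = toy_locus)), 0)
})

test_that("joint classification follows the resected and productive rules", {
  jx <- data.frame(
    donor_break = c(12000, 12000, 10001, 5200),
    acceptor_break = c(41000, 44300, 41000, 47000),
    orientation = "DEL",
    consensus_insertion_len = 0)
  cls <- classify_joint(jx, toy_locus)
  expect_equal(cls$label, c("S_S", "RESECTED", "S_S", "RESECTED"))
  expect_equal(cls$acceptor_out, c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(cls$donor_out, c(FALSE, FALSE, FALSE, TRUE))
  # coordinate-derived amplicon length and productive-length flag
  expect_equal(cls$amplicon_len_coords[1],
               (12000 - 100) + (55030 - 41000))
  expect_true(cls$productive_length[1])
  expect_false(cls$productive_length[4])
  # boundary convention: donor break at donor_S end is inside (last donor
  # base in the region); acceptor break at acceptor_S end is outside
  edge <- classify_joint(data.frame(donor_break = 14000,
                                    acceptor_break = 44000,
                                    orientation = "DEL",
                                    consensus_insertion_len = 0), toy_locus)
  expect_false(edge$donor_out)
  expect_true(edge$acceptor_out)
  # idempotence: reclassifying reproduces the labels
  expect_equal(classify_joint(cls, toy_locus)$label, cls$label)
})

test_that("sample summary computes medians, percentages and histograms", {
  jx <- classify_joint(data.frame(
    donor_break = c(rep(12000, 9), 9800),
    acceptor_break = c(seq(41000, by = 10, length.out = 9), 41000),
    orientation = "DEL", consensus_insertion_len = 0), toy_locus)
  s <- summarize_lrpcr(c(5000, 9000, 11000) * 1e0, jx, toy_locus)
  expect_equal(s$median_read_len, 9000)
  s2 <- summarize_lrpcr(c(4200, 9000, 11000) * 1e0, jx,
                        local({l <- toy_locus
                               l$thresholds$productive_min_len <- 4900; l}))
  expect_equal(s2$pct_reads_below_productive_min, 100 / 3)
  expect_equal(s$pct_unique_junctions_resected, 10)
  # histogram mass equals the number of contributing junctions
  expect_equal(sum(s$donor_hist$count), nrow(jx))
  expect_equal(sum(s$acceptor_hist$count), nrow(jx))
  expect_true(all(diff(s$donor_hist$bin_start) == 250))
  # no pass-ROI reads: counts 0, percentages absent rather than 0
  s0 <- summarize_lrpcr(numeric(0), jx[0, ], toy_locus)
  expect_equal(s0$n_reads_pass_roi, 0)
  expect_null(s0$median_read_len)
  expect_null(s0$pct_unique_junctions_resected)
})

test_that("full pipeline recovers error-free events and their signatures", {
  res <- lrpcr_pipeline(fix_reads$reads, fix_sim$locus, fix_index,
                        min_depth = 3)
  jx <- res$junctions
  key_t <- paste(fix_del$donor_break, fix_del$acceptor_break)
  key_j <- paste(jx$donor_break, jx$acceptor_break)
  expect_setequal(key_j, unique(key_t))
  expect_equal(res$summary$pct_unique_junctions_resected,
               100 * mean(fix_del$region_class == "RESECTED"))
  m <- match(key_t, key_j)
  expect_equal(jx$mh_len[m], fix_del$realized_mh)
  expect_equal(jx$consensus_insertion_len[m], fix_del$ins_len)
  expect_equal(jx$consensus_ins_seq[m], fix_del$insertion_seq)
  # amplicon length conservation: coordinate-derived length equals the
  # rendered read length when error rates are zero
  expect_equal(jx$amplicon_len_coords[m],
               unname(nchar(fix_reads$reads[paste0(fix_del$event_id, "_r01")])))
  # all reads pass the both-ends filter; depths are conserved
  expect_equal(unname(res$counts["n_reads_pass_roi"]),
               length(fix_reads$reads))
  expect_equal(sum(jx$depth), sum(fix_del$depth))
})
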