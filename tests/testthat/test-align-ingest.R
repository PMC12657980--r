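test_that("chain_align_read recovers planted segments exactly", {
  ref <- fix_sim$reference

  # identity: a read that is an exact substring maps as one '+' block
  read <- substr(ref, 2001, 8000)
  ch <- chain_align_read(read, fix_index, read_id = "ident")
  expect_equal(nrow(ch$blocks), 1)
  expect_equal(ch$blocks$strand, "+")
  expect_equal(c(ch$blocks$ref_start, ch$blocks$ref_end), c(2000, 8000))
  expect_equal(c(ch$blocks$read_start, ch$blocks$read_end), c(0, 6000))

  # two '+' segments; junction-facing boundaries may shift within the
  # junction's placement-ambiguity tract only
  seg <- function(s, e) substr(ref, s + 1, e)
  read2 <- paste0(seg(0, 5000), seg(23000, 28000))
  mh <- mh_oracle(ref, 5000, 23000, "DEL")
  ch2 <- chain_align_read(read2, fix_index, read_id = "two")
  expect_equal(nrow(ch2$blocks), 2)
  expect_true(all(ch2$blocks$strand == "+"))
  expect_equal(ch2$blocks$ref_start[1], 0)
  expect_lte(abs(ch2$blocks$ref_end[1] - 5000), mh)
  expect_lte(abs(ch2$blocks$ref_start[2] - 23000), mh)
  expect_equal(ch2$blocks$ref_end[2], 28000)

  # reverse-complemented second segment maps as a '-' block
  read3 <- paste0(seg(0, 5000), o_rc(seg(23000, 28000)))
  ch3 <- chain_align_read(read3, fix_index, read_id = "inv")
  expect_equal(ch3$blocks$strand, c("+", "-"))
  inv_mh <- mh_oracle(ref, 5000, 28000, "INV")
  expect_lte(abs(ch3$blocks$ref_end[1] - 5000), inv_mh)
  expect_equal(ch3$blocks$ref_start[2], 23000)
  expect_lte(abs(ch3$blocks$ref_end[2] - 28000), inv_mh)

  # whole-read reverse complement: same segments, strands flipped,
  # read coordinates mirrored
  ch4 <- chain_align_read(o_rc(read2), fix_index, read_id = "rc")
  expect_equal(nrow(ch4$blocks), 2)
  expect_true(all(ch4$blocks$strand == "-"))

  expect_error(chain_align_read("ACGT", fix_index), "shorter")
  # a read with no anchors yields an empty chain, not an error
  ch5 <- chain_align_read(strrep("ACGT", 100), locus_index(strrep("G", 500)))
  expect_equal(nrow(ch5$blocks), 0)
})

test_that("pipeline recovery property holds for error-free segments", {
  # generating segments recovered exactly up to MH ambiguity, across events
  for (i in sample(nrow(fix_del), 8)) {
    ev <- fix_del[i, ]
    read <- fix_reads$reads[[paste0(ev$event_id, "_r01")]]
    ch <- chain_align_read(read, fix_index)
    expect_equal(nrow(ch$blocks), 2)
    bl <- ch$blocks
    # truth coordinates are at the donor-maximal placement: the donor block
    # ends exactly at the donor break, and the acceptor block claims the
    # shared junction bases (read overlap m), so its start advanced by m is
    # the acceptor break
    m <- max(0, bl$read_end[1] - bl$read_start[2])
    expect_equal(bl$ref_end[1], ev$donor_break)
    expect_equal(bl$ref_start[2] + m, ev$acceptor_break)
  }
})

test_that("roi_filter demands both ends and is monotone in blocks", {
  lm <- fix_sim$locus
  both <- make_chain(list(c(9000, 12000, 0, 3000, "+"),
                          c(21000, 23000, 3000, 5000, "+")), 5000)
  expect_true(roi_filter(both, lm))
  donor_only <- make_chain(list(c(9000, 12000, 0, 3000, "+")), 3000)
  expect_false(roi_filter(donor_only, lm))
  empty <- both
  empty$blocks <- both$blocks[0, ]
  expect_false(roi_filter(empty, lm))
  # adding blocks never flips TRUE -> FALSE
  augmented <- both
  augmented$blocks <- rbind(both$blocks,
                            data.frame(ref_start = 1, ref_end = 200,
                                       read_start = 4000, read_end = 4199,
                                       strand = "+", matches = 199))
  expect_true(roi_filter(augmented, lm))
})

test_that("SAM records convert to chains with correct CIGAR arithmetic", {
  sam <- withr::local_tempfile(fileext = ".sam")
  glen <- toy_locus$locus$end
  writeLines(c(
    "@HD\tVN:1.6",
    sprintf("@SQ\tSN:chrT\tLN:%d", glen),
    # 100M at locus offset 500: block ref [500,600), read [0,100)
    "r1\t0\tchrT\t501\t60\t100M\t*\t0\t0\t*\t*",
    # split read: 50S100M primary + 100M50S supplementary
    "r2\t0\tchrT\t1001\t60\t50S100M\t*\t0\t0\t*\t*",
    "r2\t2048\tchrT\t2001\t60\t100M50S\t*\t0\t0\t*\t*",
    # unmapped and secondary records are ignored
    "r3\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*",
    "r4\t256\tchrT\t3001\t60\t100M\t*\t0\t0\t*\t*"
  ), sam)
  rc <- read_alignment_chains(sam, toy_locus)
  expect_named(rc$chains, c("r1", "r2"), ignore.order = TRUE)
  b1 <- rc$chains$r1$blocks
  expect_equal(c(b1$ref_start, b1$ref_end, b1$read_start, b1$read_end),
               c(500, 600, 0, 100))
  b2 <- rc$chains$r2$blocks
  expect_equal(b2$read_start, c(0, 50))
  expect_equal(b2$read_end, c(100, 150))
  expect_equal(b2$ref_start, c(2000, 1000))
  expect_equal(rc$skipped[["unmapped"]], 1)
  expect_equal(rc$skipped[["secondary"]], 1)

  # empty file (header only) -> empty result
  sam0 <- withr::local_tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6", sprintf("@SQ\tSN:chrT\tLN:%d", glen)), sam0)
  rc0 <- read_alignment_chains(sam0, toy_locus)
  expect_length(rc0$chains, 0)

  # missing sequence dictionary entry is an input error
  samx <- withr::local_tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6", "@SQ\tSN:other\tLN:1000"), samx)
  expect_error(read_alignment_chains(samx, toy_locus), "dictionary")
})

test_that("chains round-trip through the SAM writer and reader", {
  reads <- fix_reads$reads[!duplicated(sub("_r.*", "", names(fix_reads$reads)))]
  reads <- reads[1:5]
  chains <- lapply(seq_along(reads), function(i)
    chain_align_read(reads[[i]], fix_index, read_id = names(reads)[i]))
  names(chains) <- names(reads)
  sam <- withr::local_tempfile(fileext = ".sam")
  write_chains_sam(chains, fix_sim$locus, sam)
  back <- read_alignment_chains(sam, fix_sim$locus)$chains
  expect_setequal(names(back), names(chains))
  for (nm in names(chains)) {
    a <- chains[[nm]]$blocks[, c("ref_start", "ref_end", "read_start",
                                 "read_end", "strand")]
    b <- back[[nm]]$blocks[, c("ref_start", "ref_end", "read_start",
                               "read_end", "strand")]
    expect_equal(b[order(b$read_start), ], a[order(a$read_start), ],
                 ignore_attr = TRUE)
    expect_equal(back[[nm]]$read_len, chains[[nm]]$read_len)
  }
})
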