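test_that("synthetic locus is seed-deterministic with fixed coordinates", {
  p <- sim_params(seed = 5, locus_scale = 30000)
  s1 <- make_synthetic_locus(p)
  s2 <- make_synthetic_locus(p)
  expect_identical(s1$reference, s2$reference)
  s3 <- make_synthetic_locus(sim_params(seed = 6, locus_scale = 30000))
  expect_false(identical(s1$reference, s3$reference))
  expect_equal(s1$locus$donor_S, s3$locus$donor_S)
  expect_equal(s1$locus$acceptor_S, s3$locus$acceptor_S)
  expect_length(validate_locus(s1$locus), 0)
  # the germline amplicon cannot be a productive length
  expect_gt(s1$locus$primer3[2] - s1$locus$primer5[1],
            s1$locus$thresholds$productive_max_len)
  expect_error(make_synthetic_locus(sim_params(locus_scale = 20000 - 1)),
               "locus_scale")
})

test_that("donor S region is G-rich on the canonical strand", {
  dS <- fix_sim$locus$donor_S
  seg <- substr(fix_sim$reference, dS[1] + 1, dS[2])
  g_frac <- lengths(regmatches(seg, gregexpr("G", seg))) / nchar(seg)
  expect_gt(g_frac, 0.3)
})

test_that("event sampling honors degenerate parameters and determinism", {
  expect_identical(sample_events(fix_params, fix_sim$locus, fix_sim$reference),
                   fix_events)
  p0 <- sim_params(seed = 3, n_events = 100, locus_scale = 30000,
                   p_resected = 0, p_insertion = 0)
  s0 <- make_synthetic_locus(p0)
  e0 <- sample_events(p0, s0$locus, s0$reference)
  expect_true(all(e0$region_class == "S_S"))
  p1 <- sim_params(seed = 3, n_events = 100, locus_scale = 30000,
                   p_insertion = 1, insertion_len_max = 1)
  e1 <- sample_events(p1, s0$locus, s0$reference)
  expect_true(all(e1$ins_len == 1))
  expect_true(all(nchar(e1$insertion_seq) == 1))
  expect_true(all(e1$realized_mh == 0))
  # insertion and MH are mutually exclusive; realized_mh is non-negative
  expect_true(all(fix_events$realized_mh >= 0))
  expect_true(all(fix_events$realized_mh[fix_events$ins_len > 0] == 0))
  # region_class is recomputable from the coordinates
  dS <- fix_sim$locus$donor_S; aS <- fix_sim$locus$acceptor_S
  donor_out <- !(fix_events$donor_break > dS[1] &
                   fix_events$donor_break <= dS[2])
  acc_out <- !(fix_events$acceptor_break >= aS[1] &
                 fix_events$acceptor_break < aS[2])
  expect_equal(fix_events$region_class,
               ifelse(donor_out | acc_out, "RESECTED", "S_S"))
})

test_that("drawn class fractions follow their Bernoulli laws at n = 2000", {
  p <- sim_params(seed = 2024, n_events = 2000, locus_scale = 30000)
  s <- make_synthetic_locus(p)
  e <- sample_events(p, s$locus, s$reference)
  # exact binomial 99% interval for the drawn flags
  for (spec in list(list(x = sum(e$orientation == "INV"), p = p$p_inversion),
                    list(x = sum(e$resected_drawn), p = p$p_resected))) {
    ci <- stats::binom.test(spec$x, 2000, spec$p,
                            conf.level = 0.99)$conf.int
    expect_true(ci[1] <= spec$p && spec$p <= ci[2])
  }
})

test_that("error-free LR-PCR reads reconstruct their events exactly", {
  # INV events are not amplified
  expect_setequal(fix_reads$unamplified,
                  fix_events$event_id[fix_events$orientation == "INV"])
  expect_identical(
    render_lrpcr_reads(fix_events, fix_sim$reference, fix_sim$locus,
                       fix_params)$reads,
    fix_reads$reads)
  p5 <- fix_sim$locus$primer5; p3 <- fix_sim$locus$primer3
  for (i in sample(nrow(fix_del), 10)) {
    ev <- fix_del[i, ]
    rds <- fix_reads$reads[grepl(paste0(ev$event_id, "_"),
                                 names(fix_reads$reads))]
    expect_length(rds, ev$depth)
    expect_true(all(rds == rds[[1]]))
    expect_equal(nchar(rds[[1]]),
                 (ev$donor_break - p5[1]) + ev$ins_len +
                   (p3[2] - ev$acceptor_break))
    # exact string search re-derives the junction
    donor_part <- substr(fix_sim$reference, p5[1] + 1, ev$donor_break)
    expect_identical(substr(rds[[1]], 1, nchar(donor_part)), donor_part)
  }
})

test_that("substitution errors occur at the configured binomial rate", {
  p_err <- sim_params(seed = 11, n_events = 60, locus_scale = 30000,
                      depth_min = 3, depth_max = 6,
                      error_sub_rate = 0.005, error_indel_rate = 0)
  noisy <- render_lrpcr_reads(fix_events, fix_sim$reference, fix_sim$locus,
                              p_err)
  stopifnot(identical(names(noisy$reads), names(fix_reads$reads)))
  mism <- mapply(function(a, b)
    sum(utf8ToInt(a) != utf8ToInt(b)), noisy$reads, fix_reads$reads)
  n_bases <- sum(nchar(fix_reads$reads))
  expect_lt(abs(sum(mism) - 0.005 * n_bases),
            3 * sqrt(n_bases * 0.005 * 0.995))
})

test_that("HTGTS table mirrors the truth table exactly when error-free", {
  tlx <- render_htgts_table(fix_events, fix_sim$reference, fix_sim$locus,
                            fix_params)
  expect_equal(nrow(tlx), nrow(fix_events))
  expect_equal(to_canonical(fix_sim$locus, tlx$prey_coord),
               fix_events$acceptor_break)
  expect_equal(to_canonical(fix_sim$locus, tlx$bait_coord),
               fix_events$donor_break)
  del <- fix_events$orientation == "DEL"
  expect_true(all(tlx$prey_strand[del] == fix_sim$locus$del_strand))
  expect_true(all(tlx$prey_strand[!del] != fix_sim$locus$del_strand))
  # deterministic rendering
  expect_identical(render_htgts_table(fix_events, fix_sim$reference,
                                      fix_sim$locus, fix_params), tlx)
})

test_that("V(D)J junction rendering is deterministic and truth-consistent", {
  v1 <- render_vdj_junctions(fix_params)
  v2 <- render_vdj_junctions(fix_params)
  expect_identical(v1, v2)
  # a blunt full join has zero resection and zero MH only if the germline
  # flanks share nothing; verify via brute-force decomposition
  for (i in sample(length(v1$junctions), 15)) {
    or <- vdj_oracle(v1$junctions[[i]], v1$v_ref, v1$j_ref)
    expect_equal(or$v_resection, v1$truth$v_resection[i])
    expect_equal(or$j_resection, v1$truth$j_resection[i])
    expect_equal(or$mh_len, v1$truth$mh_len[i])
    expect_equal(or$ins_len, v1$truth$ins_len[i])
  }
})

test_that("plant_mh engineers a recoverable microhomology tract", {
  ref <- fix_sim$reference
  d <- 6000; a <- 21000
  ref2 <- plant_mh(ref, d, a, 3)
  expect_gte(microhomology_length(ref2, d, a, "DEL"), 3)
  expect_gte(mh_oracle(ref2, d, a, "DEL"), 3)
})
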