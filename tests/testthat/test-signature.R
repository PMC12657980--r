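test_that("microhomology_length matches constructed flank examples", {
  # donor flank ...ACGTAGCT | acceptor context ...TTTAGCT | CCC:
  # "TAGCT" is shared, so the junction is ambiguous over 6 placements
  left <- rnd_dna(40)
  mid <- paste0("A", rnd_dna(39))  # 'A' blocks rightward extension into "CCC"
  ref <- paste0(left, "ACGTAGCT", mid, "TTTAGCT", "CCC", rnd_dna(40))
  d <- nchar(left) + 8
  a <- nchar(left) + 8 + nchar(mid) + 7
  expect_equal(microhomology_length(ref, d, a, "DEL"), 5)
  expect_equal(mh_oracle(ref, d, a, "DEL"), 5)

  # no shared base
  ref0 <- paste0(strrep("A", 30), "AAAC", strrep("T", 26), "TTT", "GGT",
                 strrep("C", 30))
  expect_equal(microhomology_length(ref0, 34, 63, "DEL"), 0)

  # a 25-base shared flank is capped at mh_max = 20
  shared <- rnd_dna(25)
  refc <- paste0(rnd_dna(30), shared, rnd_dna(30), shared,
                 rnd_dna(30))
  expect_equal(microhomology_length(refc, 55, 110, "DEL", mh_max = 20), 20)

  # windows truncated at the sequence ends are compared over the overlap
  # (junction (2,6) on ACGTACGT is ambiguous over all 5 placements)
  expect_equal(microhomology_length("ACGTACGT", 2, 6, "DEL"), 4)
})

test_that("microhomology equals the placement-enumeration oracle", {
  set.seed(101)
  ref <- fix_sim$reference
  L <- nchar(ref)
  for (i in 1:300) {
    d <- sample(60:(L - 60), 1)
    a <- sample(60:(L - 60), 1)
    orient <- sample(c("DEL", "INV"), 1)
    expect_equal(microhomology_length(ref, d, a, orient),
                 mh_oracle(ref, d, a, orient),
                 info = sprintf("%s d=%d a=%d", orient, d, a))
  }
})

test_that("DEL microhomology is invariant under reverse-complement + swap", {
  set.seed(202)
  ref <- substr(fix_sim$reference, 1, 5000)
  rcref <- o_rc(ref)
  L <- nchar(ref)
  for (i in 1:100) {
    d <- sample(60:(L - 60), 1); a <- sample(60:(L - 60), 1)
    expect_equal(microhomology_length(ref, d, a, "DEL"),
                 microhomology_length(rcref, L - a, L - d, "DEL"))
  }
})

test_that("call_signature applies the direct/MH/insertion partition", {
  ref <- fix_sim$reference
  s_ins <- call_signature(ref, 6000, 21000, "DEL", ins_len = 3,
                          ins_seq = "GAT")
  expect_equal(s_ins$mh_len, 0L)
  expect_equal(s_ins$ins_len, 3L)
  expect_equal(s_ins$ins_seq, "GAT")
  expect_false(s_ins$direct)

  ref4 <- plant_mh(ref, 6000, 21000, 4)
  m4 <- microhomology_length(ref4, 6000, 21000, "DEL")
  expect_gte(m4, 4)
  s_mh <- call_signature(ref4, 6000, 21000, "DEL")
  expect_equal(s_mh$mh_len, m4)
  expect_false(s_mh$direct)

  # gap-free, no shared base on either side: a direct joint
  ref0 <- paste0(strrep("A", 99), "G", strrep("C", 99), "A", strrep("T", 50))
  s_dir <- call_signature(ref0, 100, 200, "DEL")
  expect_equal(s_dir$mh_len, 0L)
  expect_true(s_dir$direct)
})

test_that("signature summaries partition and sum consistently", {
  sig <- data.frame(mh_len = c(0, 0, 0, 0, 2, 2, 2, 2, 5, 5),
                    ins_len = 0)
  s <- signature_summary(sig)
  expect_equal(s$pct_direct, 40)
  expect_equal(s$pct_mh_ge_class, 20)
  expect_equal(sum(s$landscape$fraction), 1)
  expect_equal(s$landscape$fraction[s$landscape$mh_len == 0], 0.4)

  all_direct <- signature_summary(data.frame(mh_len = rep(0, 7), ins_len = 0))
  expect_equal(all_direct$pct_mh_ge_class, 0)
  expect_equal(all_direct$landscape$fraction[1], 1)
  expect_equal(sum(all_direct$landscape$fraction[-1]), 0)

  ins <- signature_summary(data.frame(mh_len = c(0, 0), ins_len = c(1, 3)))
  expect_equal(ins$pct_ins_gt_1bp, 50)
  expect_equal(ins$pct_insertion, 100)

  # permutation invariance and direct+MH+insertion partition
  set.seed(33)
  sig2 <- data.frame(mh_len = sample(0:6, 40, TRUE), ins_len = 0)
  sig2$ins_len[sig2$mh_len == 0][1:5] <- 2
  s_a <- signature_summary(sig2)
  s_b <- signature_summary(sig2[sample(nrow(sig2)), ])
  expect_equal(s_a, s_b)
  expect_equal(s_a$pct_direct +
                 100 * mean(sig2$mh_len > 0 & sig2$ins_len == 0) +
                 s_a$pct_insertion, 100)
  expect_error(signature_summary(sig2[0, ]), "empty")
})

test_that("V(D)J junction decomposition recovers constructed cases", {
  v <- paste0(rnd_dna(120), "GATTACA")   # known 3' end
  j <- paste0("CCGGTTA", rnd_dna(120))   # known 5' start
  # full V + full J, no shared flank (ends differ by construction)
  full <- paste0(v, j)
  r <- analyze_vdj_junction(full, v, j)
  o <- vdj_oracle(full, v, j)
  expect_equal(unclass(r)[c("v_resection", "j_resection", "mh_len", "ins_len")],
               o[c("v_resection", "j_resection", "mh_len", "ins_len")],
               ignore_attr = TRUE)

  # 4 V bases resected, 2 J bases resected, 1-base insertion "A"
  sq <- paste0(substr(v, 1, nchar(v) - 4), "A", substr(j, 3, nchar(j)))
  r2 <- analyze_vdj_junction(sq, v, j)
  o2 <- vdj_oracle(sq, v, j)
  expect_equal(r2$v_resection, o2$v_resection)
  expect_equal(r2$j_resection, o2$j_resection)
  expect_equal(r2$mh_len, o2$mh_len)
  expect_equal(r2$ins_len, o2$ins_len)

  # V and J sharing a terminal "CT" present once in the read
  v3 <- paste0(rnd_dna(60), "AGCT")
  j3 <- paste0("CTGA", rnd_dna(60))
  sq3 <- paste0(v3, substr(j3, 3, nchar(j3)))
  r3 <- analyze_vdj_junction(sq3, v3, j3)
  expect_equal(r3$mh_len, vdj_oracle(sq3, v3, j3)$mh_len)
  expect_gte(r3$mh_len, 2)

  expect_error(analyze_vdj_junction(paste0("TTTT", rnd_dna(50)),
                                    paste0("AAAA", rnd_dna(50)),
                                    paste0(rnd_dna(50), "GGGG")),
               "only one")
})

test_that("V(D)J decomposition is exact on the simulator truth table", {
  p <- sim_params(seed = 77, n_events = 120)
  vj <- render_vdj_junctions(p)
  res <- lapply(vj$junctions, analyze_vdj_junction,
                v_ref = vj$v_ref, j_ref = vj$j_ref)
  expect_equal(vapply(res, `[[`, integer(1), "v_resection"),
               vj$truth$v_resection, ignore_attr = TRUE)
  expect_equal(vapply(res, `[[`, integer(1), "j_resection"),
               vj$truth$j_resection, ignore_attr = TRUE)
  expect_equal(vapply(res, `[[`, integer(1), "mh_len"),
               vj$truth$mh_len, ignore_attr = TRUE)
  expect_equal(vapply(res, `[[`, integer(1), "ins_len"),
               vj$truth$ins_len, ignore_attr = TRUE)
})
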