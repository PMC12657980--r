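# Shared small simulation fixture, built once per test run. Error-free so
# that exact-recovery properties hold; depth 3-6 with a matching depth floor
# of 3 keeps the fixture fast.
fix_params <- sim_params(seed = 11, n_events = 60, locus_scale = 30000,
                         depth_min = 3, depth_max = 6,
                         error_sub_rate = 0, error_indel_rate = 0)
fix_sim <- make_synthetic_locus(fix_params)
fix_events <- sample_events(fix_params, fix_sim$locus, fix_sim$reference)
fix_reads <- render_lrpcr_reads(fix_events, fix_sim$reference,
                                fix_sim$locus, fix_params)
fix_index <- locus_index(fix_sim$reference)
fix_del <- fix_events[fix_events$orientation == "DEL", ]

# a deliberately simple non-repetitive locus for hand-constructed chains
toy_locus <- locus_map(
  reference_name = "toy",
  locus = list(chrom = "chrT", start = 0, end = 60000),
  canonical_strand = "+",
  primer5 = c(100, 130), primer3 = c(55000, 55030),
  donor_S = c(10000, 14000), acceptor_S = c(40000, 44000),
  roi_pad = 5000, junction_pad = 10000,
  bait_site = 9800,
  thresholds = list(productive_min_len = 20900, productive_max_len = 29000,
                    label = "toy")
)

make_chain <- function(blocks, read_len, read_id = "r") {
  bl <- do.call(rbind, lapply(blocks, function(b)
    data.frame(ref_start = b[1], ref_end = b[2], read_start = b[3],
               read_end = b[4], strand = b[5],
               matches = as.numeric(b[4]) - as.numeric(b[3]))))
  for (col in c("ref_start", "ref_end", "read_start", "read_end", "matches"))
    bl[[col]] <- as.numeric(bl[[col]])
  bl <- bl[order(bl$read_start), ]
  rownames(bl) <- NULL
  structure(list(read_id = read_id, read_len = read_len, blocks = bl),
            class = "alignment_chain")
}
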