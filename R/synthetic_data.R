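# Seeded simulator of class-switch-recombination events on a miniature
# switch locus. The generator defines the study conditions the validation
# suite runs under: a repeat-rich, G-rich donor (S-mu-like) and acceptor
# (S-gamma1-like) region flanked by primer sites, deletional and
# inversional joins, resection tracts extending beyond the S borders
# (geometric length), junction microhomology arising from sequence context,
# untemplated insertions, per-event read depth, and CCS-like sequencing
# error (substitutions and 1-bp indels).
#
# Truth tables report junction coordinates at the canonical donor-maximal
# placement (a junction inside a microhomology tract is only defined up to
# placement), which is the placement the breakpoint caller reports; the
# drawn Bernoulli class flags are kept alongside in *_drawn columns.

#' Simulation parameters
#'
#' Defaults emulate the event-class proportions of an NHEJ-deficient
#' (Xrcc4-null-like) switch-junction library: 12% inversional joins and a
#' 13% resected fraction, with CCS-like error rates.
#'
#' @param seed Integer seed; every generator output is a pure function of it.
#' @param n_events Number of recombination events.
#' @param p_inversion Probability that an event is inversional.
#' @param p_resected Probability that at least one break is displaced beyond
#'   its S-region border.
#' @param resection_mean Mean (bp) of the geometric tract length beyond the
#'   S border, per resected end.
#' @param p_insertion Probability of an untemplated insertion at the
#'   junction.
#' @param insertion_len_max Maximum insertion length (uniform 1..max).
#' @param depth_min,depth_max Reads per event (uniform).
#' @param error_sub_rate,error_indel_rate Per-base substitution and 1-bp
#'   indel probabilities of the CCS error model (each <= 0.05).
#' @param locus_scale Total synthetic locus length in bp (>= 20000).
#' @return A validated list of class `sim_params`.
#' @export
sim_params <- function(seed = 1, n_events = 2000, p_inversion = 0.12,
                       p_resected = 0.13, resection_mean = 500,
                       p_insertion = 0.15, insertion_len_max = 10,
                       depth_min = 10, depth_max = 20,
                       error_sub_rate = 0.002, error_indel_rate = 0.0005,
                       locus_scale = 60000) {
  p <- list(seed = as.integer(seed), n_events = as.integer(n_events),
            p_inversion = p_inversion, p_resected = p_resected,
            resection_mean = resection_mean, p_insertion = p_insertion,
            insertion_len_max = as.integer(insertion_len_max),
            depth_min = as.integer(depth_min),
            depth_max = as.integer(depth_max),
            error_sub_rate = error_sub_rate,
            error_indel_rate = error_indel_rate,
            locus_scale = as.integer(locus_scale))
  probs <- c(p$p_inversion, p$p_resected, p$p_insertion)
  if (any(probs < 0 | probs > 1)) stopf("probabilities must lie in [0, 1]")
  if (p$depth_min < 1 || p$depth_max < p$depth_min)
    stopf("require 1 <= depth_min <= depth_max")
  if (p$error_sub_rate < 0 || p$error_sub_rate > 0.05 ||
      p$error_indel_rate < 0 || p$error_indel_rate > 0.05)
    stopf("error rates must lie in [0, 0.05]")
  structure(p, class = "sim_params")
}

# switch-repeat-like sequence: G-rich pentamer units with per-base variation
s_region_seq <- function(len, mut_rate = 0.05) {
  units <- c("GAGCT", "GGGGT", "GGGCT", "GGGGA", "GCTGG")
  s <- paste(sample(units, ceiling(len / 5), replace = TRUE), collapse = "")
  s <- substr(s, 1, len)
  nmut <- stats::rbinom(1, len, mut_rate)
  if (nmut > 0) {
    pos <- sample.int(len, nmut)
    ch <- strsplit(s, "")[[1]]
    ch[pos] <- sample(c("A", "C", "G", "T"), nmut, replace = TRUE)
    s <- paste(ch, collapse = "")
  }
  s
}

#' Generate a miniature switch locus
#'
#' Builds a synthetic canonical-strand reference containing, in order: a 5'
#' primer footprint, a donor S region of G-rich tandem pentamer repeats
#' with per-base variation, a spacer, an acceptor S region of the same
#' repeat family, a spacer, and a 3' primer footprint — together with the
#' matching [locus_map()] (regions of interest, HTGTS bait site, and
#' productive-amplicon thresholds scaled to the locus so that every
#' strictly S-S join is productive-length and the germline primer-to-primer
#' span exceeds the productive maximum). Feature coordinates depend only on
#' `locus_scale`; sequence content on the seed.
#'
#' @param params A [sim_params()].
#' @return List with `reference` (character sequence) and `locus`
#'   (`locus_map`).
#' @export
make_synthetic_locus <- function(params) {
  S <- params$locus_scale
  if (S < 20000) stopf("locus_scale must be >= 20000 to fit all features")
  set.seed(params$seed)
  p5 <- c(100, 130)
  dS <- c(round(S / 6), round(S / 6) + round(S / 15))
  aS <- c(round(2 * S / 3), round(2 * S / 3) + round(S / 15))
  p3 <- c(S - 5000, S - 4970)
  gap <- aS[1] - dS[2]
  roi_pad <- min(5000, floor(gap / 2) - 50, dS[1] - p5[2] - 50)
  junction_pad <- min(10000, gap - 100, S - 100 - aS[2])

  base <- random_dna(S)
  ref <- paste0(s_sub(base, 0, dS[1]),
                s_region_seq(dS[2] - dS[1]),
                s_sub(base, dS[2], aS[1]),
                s_region_seq(aS[2] - aS[1]),
                s_sub(base, aS[2], S))
  stopifnot(nchar(ref) == S)

  min_ss <- (dS[1] + 1 - p5[1]) + (p3[2] - aS[2] + 1)
  max_ss <- (dS[2] - p5[1]) + (p3[2] - aS[1]) + params$insertion_len_max
  locus <- locus_map(
    reference_name = "synthetic_switch_locus",
    locus = list(chrom = "chrS", start = 100000, end = 100000 + S),
    canonical_strand = "+",
    primer5 = p5, primer3 = p3, donor_S = dS, acceptor_S = aS,
    roi_pad = roi_pad, junction_pad = junction_pad,
    bait_site = dS[1] - 200, bait_strand = "+",
    thresholds = list(productive_min_len = min_ss - 1,
                      productive_max_len = max_ss + 1,
                      label = "synthetic-IgG1"),
    del_strand = "+"
  )
  list(reference = ref, locus = locus)
}

# draw an insertion whose boundary bases cannot extend flanking homology,
# so truth coordinates stay identifiable from rendered molecules
draw_insertion <- function(len, donor_next, acceptor_prev) {
  bases <- c("A", "C", "G", "T")
  ins <- sample(bases, len, replace = TRUE)
  ins[1] <- sample(setdiff(bases, donor_next), 1)
  if (len > 1) {
    ins[len] <- sample(setdiff(bases, acceptor_prev), 1)
  } else if (ins[1] == acceptor_prev) {
    ins[1] <- sample(setdiff(bases, c(donor_next, acceptor_prev)), 1)
  }
  paste(ins, collapse = "")
}

ref_base <- function(reference, pos0) substr(reference, pos0 + 1, pos0 + 1)

#' Sample ground-truth recombination events
#'
#' Draws `n_events` events on a synthetic locus: orientation (DEL/INV with
#' probability `p_inversion`), break coordinates (uniform within the S
#' regions, or displaced beyond an S border by a geometric resection tract
#' with probability `p_resected`; the resected side is donor, acceptor or
#' both with weights 0.4/0.4/0.2), untemplated insertions, per-event depth,
#' and the realized junction microhomology implied by the reference
#' sequence. Coordinates are reported at the canonical donor-maximal
#' placement; `region_class` and the `*_out` flags are recomputed from
#' those coordinates (the drawn Bernoulli flags are kept in `*_drawn`
#' columns).
#'
#' @param params A [sim_params()].
#' @param locus,reference Output of [make_synthetic_locus()].
#' @return Data frame of events (`event_id`, `orientation`, `donor_break`,
#'   `acceptor_break`, `region_class`, `donor_out`, `acceptor_out`,
#'   `resected_drawn`, `insertion_seq`, `ins_len`, `realized_mh`, `depth`).
#' @export
sample_events <- function(params, locus, reference) {
  set.seed(params$seed + 1L)
  n <- params$n_events
  dS <- locus$donor_S; aS <- locus$acceptor_S
  tract_cap <- locus$roi_pad - 100

  orientation <- ifelse(stats::runif(n) < params$p_inversion, "INV", "DEL")
  resected <- stats::runif(n) < params$p_resected
  side <- ifelse(resected,
                 sample(c("donor", "acceptor", "both"), n, replace = TRUE,
                        prob = c(0.4, 0.4, 0.2)),
                 "none")
  donor_res <- side %in% c("donor", "both")
  acc_res <- side %in% c("acceptor", "both")

  d <- integer(n); a <- integer(n)
  d[!donor_res] <- sample(seq(dS[1] + 1, dS[2]), sum(!donor_res),
                          replace = TRUE)
  d[donor_res] <- dS[1] - rgeom_tract(sum(donor_res), params$resection_mean,
                                      cap = tract_cap) + 1L
  a[!acc_res] <- sample(seq(aS[1], aS[2] - 1), sum(!acc_res), replace = TRUE)
  a[acc_res] <- aS[2] - 1L + rgeom_tract(sum(acc_res), params$resection_mean,
                                         cap = tract_cap)

  has_ins <- stats::runif(n) < params$p_insertion
  ins_len <- ifelse(has_ins,
                    sample.int(params$insertion_len_max, n, replace = TRUE),
                    0L)
  ins_seq <- character(n)
  mh <- integer(n)
  for (i in seq_len(n)) {
    if (has_ins[i]) {
      acc_prev <- if (orientation[i] == "DEL") ref_base(reference, a[i] - 1)
                  else comp_string(ref_base(reference, a[i]))
      ins_seq[i] <- draw_insertion(ins_len[i], ref_base(reference, d[i]),
                                   acc_prev)
      mh[i] <- 0L
    } else {
      cj <- canonical_junction(reference, d[i], a[i], orientation[i])
      d[i] <- cj$donor_break; a[i] <- cj$acceptor_break
      mh[i] <- cj$mh
    }
  }

  donor_out <- !(d > dS[1] & d <= dS[2])
  acceptor_out <- !(a >= aS[1] & a < aS[2])
  data.frame(
    event_id = sprintf("ev%04d", seq_len(n)),
    orientation = orientation,
    donor_break = d,
    acceptor_break = a,
    region_class = ifelse(donor_out | acceptor_out, "RESECTED", "S_S"),
    donor_out = donor_out,
    acceptor_out = acceptor_out,
    resected_drawn = resected,
    insertion_seq = ins_seq,
    ins_len = as.integer(ins_len),
    realized_mh = mh,
    depth = sample(seq(params$depth_min, params$depth_max), n,
                   replace = TRUE),
    stringsAsFactors = FALSE
  )
}

# CCS error model: independent per-base substitutions and 1-bp indels
apply_ccs_errors <- function(seq, sub_rate, indel_rate) {
  n <- nchar(seq)
  nsub <- stats::rbinom(1, n, sub_rate)
  nind <- stats::rbinom(1, n, indel_rate)
  if (nsub == 0 && nind == 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  bases <- c("A", "C", "G", "T")
  if (nsub > 0) {
    pos <- sample.int(n, nsub)
    ch[pos] <- vapply(ch[pos],
                      function(b) sample(setdiff(bases, b), 1), character(1))
  }
  if (nind > 0) {
    pos <- sort(sample.int(n, nind), decreasing = TRUE)
    del <- stats::runif(nind) < 0.5
    for (j in seq_len(nind)) {
      if (del[j]) ch <- ch[-pos[j]]
      else ch <- append(ch, sample(bases, 1), after = pos[j])
    }
  }
  paste(ch, collapse = "")
}

#' Render LR-PCR amplicon reads for deletional events
#'
#' Long-range PCR with two fixed same-sense primers amplifies deletional
#' recombination products only, so INV events are returned in the
#' `unamplified` list instead of as reads. Each DEL event yields `depth`
#' copies of the recombined amplicon — canonical reference from the 5'
#' primer start to the donor break, then the insertion, then from the
#' acceptor break to the 3' primer end — with CCS-like errors applied at
#' the configured rates.
#'
#' @param events Event table from [sample_events()].
#' @param reference,locus Output of [make_synthetic_locus()].
#' @param params A [sim_params()].
#' @return List with `reads` (named character vector, names
#'   `<event_id>_r<j>`) and `unamplified` (event ids of INV events).
#' @export
render_lrpcr_reads <- function(events, reference, locus, params) {
  set.seed(params$seed + 2L)
  p5 <- locus$primer5; p3 <- locus$primer3
  del <- events[events$orientation == "DEL", , drop = FALSE]
  if (nrow(del)) {
    bad <- del$donor_break < p5[2] | del$acceptor_break >= p3[1]
    if (any(bad))
      stopf("event coordinates outside the amplifiable interval: %s",
            paste(del$event_id[bad], collapse = ", "))
  }
  reads <- vector("list", nrow(del))
  for (i in seq_len(nrow(del))) {
    amp <- paste0(s_sub(reference, p5[1], del$donor_break[i]),
                  del$insertion_seq[i],
                  s_sub(reference, del$acceptor_break[i], p3[2]))
    dp <- del$depth[i]
    if (params$error_sub_rate > 0 || params$error_indel_rate > 0) {
      rd <- vapply(seq_len(dp), function(j)
        apply_ccs_errors(amp, params$error_sub_rate,
                         params$error_indel_rate), character(1))
    } else {
      rd <- rep(amp, dp)
    }
    names(rd) <- sprintf("%s_r%02d", del$event_id[i], seq_len(dp))
    reads[[i]] <- rd
  }
  list(reads = unlist(reads),
       unamplified = events$event_id[events$orientation == "INV"])
}

#' Write reads as FASTQ
#'
#' @param reads Named character vector of read sequences.
#' @param path Output FASTQ path.
#' @param qual Constant per-base quality character (default `"I"`, Q40).
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(reads, path, qual = "I") {
  x <- Biostrings::DNAStringSet(reads)
  q <- Biostrings::BStringSet(vapply(nchar(reads), function(n)
    strrep(qual, n), character(1)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Render an HTGTS-style junction table
#'
#' One TLX-like row per event: bait coordinate at the donor break, prey
#' coordinate at the acceptor break (genome frame), prey strand equal to
#' the locus `del_strand` for deletional joins and its opposite for
#' inversional joins, plus a junction-context sequence window.
#'
#' @param events Event table from [sample_events()].
#' @param reference,locus Output of [make_synthetic_locus()].
#' @param params A [sim_params()].
#' @param context_width Bases of context on each side of the junction
#'   (default 40).
#' @return Data frame with columns `read_id`, `bait_chrom`, `bait_coord`,
#'   `bait_strand`, `prey_chrom`, `prey_coord`, `prey_strand`,
#'   `junction_context`.
#' @export
render_htgts_table <- function(events, reference, locus, params,
                               context_width = 40) {
  w <- context_width
  opp <- function(s) ifelse(s == "+", "-", "+")
  ctx <- character(nrow(events))
  for (i in seq_len(nrow(events))) {
    d <- events$donor_break[i]; a <- events$acceptor_break[i]
    acc <- if (events$orientation[i] == "DEL") s_sub(reference, a, a + w)
           else rc_string(s_sub(reference, a - w, a))
    ctx[i] <- paste0(s_sub(reference, d - w, d), events$insertion_seq[i], acc)
  }
  gstrand <- locus$canonical_strand
  data.frame(
    read_id = events$event_id,
    bait_chrom = locus$locus$chrom,
    bait_coord = to_genome(locus, events$donor_break),
    bait_strand = gstrand,
    prey_chrom = locus$locus$chrom,
    prey_coord = to_genome(locus, events$acceptor_break),
    prey_strand = ifelse(events$orientation == "DEL", locus$del_strand,
                         opp(locus$del_strand)),
    junction_context = ctx,
    stringsAsFactors = FALSE
  )
}

#' Render simulated V(D)J Sanger junctions
#'
#' Generates germline V and J segment references and `n_events` junction
#' sequences, each a V prefix with `v_resection` bases removed from its 3'
#' end, an optional untemplated insertion, and a J suffix with
#' `j_resection` bases removed from its 5' end. The truth table reports
#' resections, microhomology and insertion length at the analyzer's
#' canonical V-maximal placement (junction bases consistent with both
#' germline templates are microhomology).
#'
#' @param params A [sim_params()]; uses `n_events`, `p_insertion`,
#'   `insertion_len_max` and the seed.
#' @param v_len,j_len Germline segment lengths (default 300).
#' @param resection_mean Mean resection per side in bp (default 4;
#'   Sanger-scale coding-joint processing).
#' @return List with `v_ref`, `j_ref` (character), `junctions` (named
#'   character vector) and `truth` (data frame `seq_id`, `v_resection`,
#'   `j_resection`, `mh_len`, `ins_len`).
#' @export
render_vdj_junctions <- function(params, v_len = 300, j_len = 300,
                                 resection_mean = 4) {
  set.seed(params$seed + 4L)
  v_ref <- random_dna(v_len)
  j_ref <- random_dna(j_len)
  n <- params$n_events
  p <- 1 / (1 + resection_mean)
  v_res <- pmin(stats::rgeom(n, p), 30L)
  j_res <- pmin(stats::rgeom(n, p), 30L)
  has_ins <- stats::runif(n) < params$p_insertion
  ins_cap <- min(params$insertion_len_max, 8L)
  seqs <- character(n)
  truth <- data.frame(seq_id = sprintf("vdj%04d", seq_len(n)),
                      v_resection = 0L, j_resection = 0L,
                      mh_len = 0L, ins_len = 0L)
  for (i in seq_len(n)) {
    vk <- v_len - v_res[i]
    v_part <- substr(v_ref, 1, vk)
    j_part <- substr(j_ref, j_res[i] + 1, j_len)
    if (has_ins[i]) {
      len <- sample.int(ins_cap, 1)
      donor_next <- if (v_res[i] > 0) substr(v_ref, vk + 1, vk + 1) else ""
      acc_prev <- if (j_res[i] > 0) substr(j_ref, j_res[i], j_res[i]) else ""
      ins <- draw_insertion(len, donor_next, acc_prev)
      seqs[i] <- paste0(v_part, ins, j_part)
      truth$v_resection[i] <- v_res[i]
      truth$j_resection[i] <- j_res[i]
      truth$ins_len[i] <- len
    } else {
      # ambiguity of the blunt join against the two germline templates
      er_cap <- min(v_res[i], j_len - j_res[i])
      ext_r <- lead_match(s_sub(j_ref, j_res[i], j_res[i] + er_cap),
                          s_sub(v_ref, vk, vk + er_cap))
      el_cap <- min(j_res[i], vk)
      ext_l <- lead_match(rev_string(s_sub(v_ref, vk - el_cap, vk)),
                          rev_string(s_sub(j_ref, j_res[i] - el_cap,
                                           j_res[i])))
      seqs[i] <- paste0(v_part, j_part)
      truth$v_resection[i] <- v_res[i] - ext_r
      truth$j_resection[i] <- j_res[i] + ext_r
      truth$mh_len[i] <- ext_l + ext_r
    }
  }
  names(seqs) <- truth$seq_id
  list(v_ref = v_ref, j_ref = j_ref, junctions = seqs, truth = truth)
}

#' Engineer a microhomology tract at a junction (testing aid)
#'
#' Rewrites the bases immediately 5' of the acceptor break so that they
#' match the donor flank for exactly `m` bases, planting a controlled MH
#' tract for signature tests.
#'
#' @param reference Canonical-strand reference.
#' @param d,a Junction coordinates (DEL orientation).
#' @param m Desired MH length (> 0).
#' @return Modified reference sequence.
#' @export
plant_mh <- function(reference, d, a, m) {
  stopifnot(m > 0, a - m >= 0, d - m >= 0)
  donor_flank <- s_sub(reference, d - m, d)
  out <- paste0(s_sub(reference, 0, a - m), donor_flank,
                s_sub(reference, a, nchar(reference)))
  # ensure the tract does not extend further on either side
  stopifnot(nchar(out) == nchar(reference))
  out
}
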