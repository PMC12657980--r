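# Breakpoint calling from ROI-passing alignment chains of LR-PCR amplicon
# reads, deduplication to unique junctions with a sequencing-depth floor,
# joint classification (S-S vs resected, productive-length), and per-sample
# summaries (median read length, binned junction distributions).

flip_chain <- function(chain) {
  bl <- chain$blocks
  rs <- chain$read_len - bl$read_end
  re <- chain$read_len - bl$read_start
  bl$read_start <- rs; bl$read_end <- re
  bl$strand <- ifelse(bl$strand == "+", "-", "+")
  bl <- bl[order(bl$read_start, bl$read_end), , drop = FALSE]
  rownames(bl) <- NULL
  chain$blocks <- bl
  chain
}

block_overlaps <- function(bl, win) bl$ref_start < win[2] & win[1] < bl$ref_end

# Re-score every junction placement j in a window around the block
# boundaries: cost(j) = mismatches of read[..j) along the donor diagonal +
# mismatches of read[j..) along the acceptor diagonal. An isolated
# sequencing error near the junction adds a constant to all placements, so
# the donor-maximal minimizer recovers the true junction; inside a
# microhomology tract the cost is flat and the maximal j is the canonical
# donor-maximal placement.
refine_junction <- function(read, reference, donor, acceptor, pad = 25) {
  L <- nchar(reference)
  dd <- donor$ref_end - donor$read_end          # donor diagonal offset
  lo <- max(donor$read_start + 1, donor$read_end - pad)
  hi <- min(acceptor$read_end - 1, acceptor$read_start + pad)
  if (acceptor$strand == "+") {
    da <- acceptor$ref_start - acceptor$read_start
    lo <- max(lo, 1 - da, 1 - dd)
    hi <- min(hi, L - da, L - dd, nchar(read))
  } else {
    ka <- acceptor$ref_end - 1 + acceptor$read_start
    lo <- max(lo, 1 - dd, ka - L + 1)
    hi <- min(hi, L - dd, ka, nchar(read))
  }
  if (hi <= lo) return(NULL)
  p <- lo:(hi - 1)                               # 0-based read positions
  rd <- utf8ToInt(substr(read, lo + 1, hi))
  md <- rd != utf8ToInt(substr(reference, lo + dd + 1, hi + dd))
  if (acceptor$strand == "+") {
    ma <- rd != utf8ToInt(substr(reference, lo + da + 1, hi + da))
  } else {
    acc <- comp_string(rev_string(substr(reference, ka - hi + 2, ka - lo + 1)))
    ma <- rd != utf8ToInt(acc)
  }
  # junction j in lo..hi: donor mismatches over [lo, j), acceptor over [j, hi)
  cost <- c(0, cumsum(md)) + rev(c(0, cumsum(rev(ma))))
  jstar <- lo + max(which(cost == min(cost))) - 1
  list(cost = min(cost), j = jstar,
       donor_break = jstar + dd,
       acceptor_break = if (acceptor$strand == "+") jstar + da
                        else ka - jstar + 1)
}

#' Extract the breakpoint call from one alignment chain
#'
#' The donor block is the roi5-overlapping block containing the read's 5'
#' (primer-proximal) end and the acceptor block the roi3-overlapping block
#' containing the 3' end; chains from reverse-sequenced reads are flipped
#' to canonical orientation first. The donor break is the donor block's
#' canonical end, the acceptor break the acceptor block's junction-proximal
#' boundary; the joint is deletional when the two blocks share a strand and
#' inversional otherwise. When the two blocks overlap on the read by m
#' bases (microhomology ambiguity) the placement is resolved donor-maximal:
#' the acceptor block is advanced by m and m recorded as `mh_ambiguity`. A
#' positive read gap between the blocks is the untemplated-insertion
#' candidate. Intermediate blocks (e.g. intra-S-mu deletions) are reported
#' as secondary junctions. Chains with more than `max_blocks` blocks, or
#' whose ends cannot be assigned, are flagged complex and excluded by the
#' caller.
#'
#' When both `read` and `reference` are supplied, a positive gap is
#' re-scored over all junction placements (see the vignette): if a single
#' isolated sequencing error explains the gap (placement cost <= 1, less
#' than the gap length) the refined junction is called instead of an
#' insertion; real untemplated insertions (cost >= 2) are preserved.
#'
#' @param chain An `alignment_chain` passing [roi_filter()].
#' @param locus A [locus_map()].
#' @param read Optional read sequence (as sequenced) to recover insertion
#'   bases.
#' @param reference Optional canonical reference for junction refinement.
#' @param max_blocks Maximum tolerated blocks per chain (default 4).
#' @return A list of class `breakpoint_call`; `$complex` is `TRUE` when the
#'   chain was excluded (with `$reason`).
#' @export
extract_breakpoint <- function(chain, locus, read = NULL, reference = NULL,
                               max_blocks = 4) {
  complex_call <- function(reason) {
    structure(list(read_id = chain$read_id, complex = TRUE, reason = reason),
              class = "breakpoint_call")
  }
  bl <- chain$blocks
  if (!roi_filter(chain, locus))
    stopf("chain %s does not pass the both-ends ROI filter", chain$read_id)
  if (nrow(bl) > max_blocks) return(complex_call("max_blocks"))

  in5 <- block_overlaps(bl, locus$roi5_window)
  in3 <- block_overlaps(bl, locus$roi3_window)
  first <- which.min(bl$read_start)
  if (!in5[first] && in3[first]) {
    chain <- flip_chain(chain)
    if (!is.null(read)) read <- rc_string(read)
    bl <- chain$blocks
    in5 <- block_overlaps(bl, locus$roi5_window)
    in3 <- block_overlaps(bl, locus$roi3_window)
  }
  di <- which(in5)[which.min(bl$read_start[in5])]
  ai <- which(in3)[which.max(bl$read_end[in3])]
  if (length(di) == 0 || length(ai) == 0) return(complex_call("ends"))
  if (di == ai) return(complex_call("single_block"))
  if (bl$strand[di] != "+") return(complex_call("donor_strand"))

  orientation <- if (bl$strand[ai] == bl$strand[di]) "DEL" else "INV"
  gap <- bl$read_start[ai] - bl$read_end[di]
  m <- max(0, -gap)
  a_ref_start <- bl$ref_start[ai]; a_ref_end <- bl$ref_end[ai]
  if (m > 0) {
    if (bl$strand[ai] == "+") a_ref_start <- a_ref_start + m
    else a_ref_end <- a_ref_end - m
  }
  donor_break <- bl$ref_end[di]
  acceptor_break <- if (orientation == "DEL") a_ref_start else a_ref_end
  ins_len <- max(0, gap)
  ins_seq <- ""
  if (ins_len > 0 && !is.null(read))
    ins_seq <- s_sub(read, bl$read_end[di], bl$read_start[ai])
  if (gap <= 0 && !is.null(read) && !is.null(reference)) {
    # gap-free or overlapping blocks: re-score placements so that a
    # sequencing error inside the microhomology tract still yields the
    # canonical donor-maximal junction. Positive gaps (insertion
    # candidates) are never re-scored — a chance diagonal match could
    # silently delete a real untemplated insertion.
    rj <- refine_junction(read, reference,
                          donor = as.list(bl[di, ]),
                          acceptor = as.list(bl[ai, ]))
    if (!is.null(rj)) {
      donor_break <- rj$donor_break
      acceptor_break <- rj$acceptor_break
    }
  }

  mid <- setdiff(order(bl$read_start), c(di, ai))
  mid <- mid[bl$read_start[mid] > bl$read_start[di] &
               bl$read_start[mid] < bl$read_start[ai]]
  secondary <- lapply(mid, function(i) {
    cand <- c(di, mid)
    cand <- cand[bl$read_start[cand] < bl$read_start[i]]
    prev <- cand[which.max(bl$read_start[cand])]
    c(from = bl$ref_end[prev], to = bl$ref_start[i])
  })

  structure(list(
    read_id = chain$read_id,
    donor_break = donor_break,
    acceptor_break = acceptor_break,
    orientation = orientation,
    gap_read_bases = gap,
    ins_len = ins_len,
    ins_seq = ins_seq,
    mh_ambiguity = m,
    amplicon_len = chain$read_len,
    n_secondary = length(secondary),
    secondary = secondary,
    complex = FALSE
  ), class = "breakpoint_call")
}

#' Collect breakpoint calls into a data frame
#'
#' @param calls List of [extract_breakpoint()] results.
#' @return Data frame, one row per non-complex call, plus an attribute
#'   `n_complex` with the excluded-call count.
#' @export
breakpoint_calls_df <- function(calls) {
  ok <- !vapply(calls, `[[`, logical(1), "complex")
  df <- do.call(rbind, lapply(calls[ok], function(cl)
    data.frame(read_id = cl$read_id, donor_break = cl$donor_break,
               acceptor_break = cl$acceptor_break,
               orientation = cl$orientation,
               gap_read_bases = cl$gap_read_bases, ins_len = cl$ins_len,
               ins_seq = cl$ins_seq, mh_ambiguity = cl$mh_ambiguity,
               amplicon_len = cl$amplicon_len,
               n_secondary = cl$n_secondary,
               stringsAsFactors = FALSE)))
  if (is.null(df))
    df <- data.frame(read_id = character(0), donor_break = numeric(0),
                     acceptor_break = numeric(0), orientation = character(0),
                     gap_read_bases = numeric(0), ins_len = numeric(0),
                     ins_seq = character(0), mh_ambiguity = numeric(0),
                     amplicon_len = numeric(0), n_secondary = numeric(0))
  attr(df, "n_complex") <- sum(!ok)
  df
}

mode_value <- function(x) {
  if (!length(x)) return(NA)
  tb <- sort(table(x), decreasing = TRUE)
  v <- names(tb)[tb == tb[1]]
  v <- sort(v)[1]
  if (is.numeric(x)) as.numeric(v) else v
}

#' Deduplicate breakpoint calls to unique junctions with a depth floor
#'
#' Groups calls by the junction key (donor break, acceptor break,
#' orientation), counts supporting reads as depth, keeps keys with depth at
#' least `min_depth` (the >= 10x unique-breakpoint rule that counteracts
#' LR-PCR amplification bias), and removes keys matching a blocklist entry
#' (within `blocklist_tol` bp, default exact) — e.g. the rearranged
#' non-productive allele of a cell line. Consensus insertion length and
#' sequence are majority votes over the group; microhomology is computed
#' from the reference at the consensus coordinates (or by majority vote
#' over the per-read ambiguity when no reference is supplied).
#'
#' Before the depth floor is applied, keys supported by at most
#' `rescue_max_depth` reads that lie within `rescue_tol` bp (both
#' coordinates, same orientation) of a key with at least 5 reads are folded
#' into that key: isolated sequencing errors near a junction scatter single
#' reads onto nearby spurious keys, and this reassigns them to the junction
#' they came from. `rescue_tol = 0` (the default) disables the rescue, so
#' grouping is exactly by key.
#'
#' @param calls Data frame from [breakpoint_calls_df()] (optionally with a
#'   `n_reads` weight column for pre-collapsed identical reads).
#' @param min_depth Depth floor (default 10).
#' @param locus A [locus_map()] (supplies the blocklist).
#' @param reference Optional canonical reference for MH computation.
#' @param blocklist_tol Coordinate tolerance for blocklist matching.
#' @param mh_max MH cap (default 20).
#' @param rescue_tol Coordinate tolerance (bp) for folding error-scattered
#'   minority keys into a well-supported neighbor (default 0: off).
#' @param rescue_max_depth Maximum depth of a key eligible for folding
#'   (default 2).
#' @return Data frame of unique junctions: `donor_break`, `acceptor_break`,
#'   `orientation`, `depth`, `consensus_insertion_len`, `consensus_ins_seq`,
#'   `mh_len`, `single_read_signature` (flag: signature from < 2 reads).
#' @export
dedup_and_filter <- function(calls, min_depth = 10, locus = NULL,
                             reference = NULL, blocklist_tol = 0,
                             mh_max = 20, rescue_tol = 0,
                             rescue_max_depth = 2) {
  if (!is.data.frame(calls)) calls <- breakpoint_calls_df(calls)
  if (!nrow(calls)) {
    return(data.frame(donor_break = numeric(0), acceptor_break = numeric(0),
                      orientation = character(0), depth = numeric(0),
                      consensus_insertion_len = numeric(0),
                      consensus_ins_seq = character(0),
                      mh_len = numeric(0),
                      single_read_signature = logical(0)))
  }
  w <- calls$n_reads %||% rep(1, nrow(calls))
  key <- paste(calls$donor_break, calls$acceptor_break, calls$orientation,
               sep = "|")
  groups <- split(seq_len(nrow(calls)), key)
  rows <- lapply(groups, function(ix) {
    depth <- sum(w[ix])
    ins_votes <- rep(calls$ins_len[ix], w[ix])
    cons_ins <- mode_value(ins_votes)
    cons_seq <- ""
    if (cons_ins > 0) {
      seqs <- rep(calls$ins_seq[ix], w[ix])
      seqs <- seqs[nchar(seqs) == cons_ins]
      if (length(seqs)) cons_seq <- mode_value(seqs)
    }
    data.frame(donor_break = calls$donor_break[ix[1]],
               acceptor_break = calls$acceptor_break[ix[1]],
               orientation = calls$orientation[ix[1]],
               depth = depth,
               consensus_insertion_len = cons_ins,
               consensus_ins_seq = cons_seq,
               mh_len = mode_value(rep(calls$mh_ambiguity[ix], w[ix])),
               single_read_signature = depth < 2,
               stringsAsFactors = FALSE)
  })
  jx <- do.call(rbind, rows)
  rownames(jx) <- NULL
  if (rescue_tol > 0 && nrow(jx) > 1) {
    minor <- which(jx$depth <= rescue_max_depth)
    major <- which(jx$depth >= 5)
    drop_ix <- integer(0)
    for (i in minor) {
      if (!length(major)) break
      dd <- abs(jx$donor_break[i] - jx$donor_break[major])
      da <- abs(jx$acceptor_break[i] - jx$acceptor_break[major])
      ok <- dd <= rescue_tol & da <= rescue_tol &
        jx$orientation[major] == jx$orientation[i]
      if (!any(ok)) next
      host <- major[ok][which.min((dd + da)[ok])]
      jx$depth[host] <- jx$depth[host] + jx$depth[i]
      drop_ix <- c(drop_ix, i)
    }
    if (length(drop_ix)) jx <- jx[-drop_ix, , drop = FALSE]
  }
  jx <- jx[jx$depth >= min_depth, , drop = FALSE]
  bl <- if (is.null(locus)) NULL else locus$blocklist
  if (!is.null(bl) && nrow(bl) && nrow(jx)) {
    hit <- vapply(seq_len(nrow(jx)), function(i)
      any(abs(jx$donor_break[i] - bl$donor_break) <= blocklist_tol &
            abs(jx$acceptor_break[i] - bl$acceptor_break) <= blocklist_tol),
      logical(1))
    jx <- jx[!hit, , drop = FALSE]
  }
  if (!is.null(reference) && nrow(jx)) {
    jx$mh_len <- vapply(seq_len(nrow(jx)), function(i) {
      if (jx$consensus_insertion_len[i] > 0) return(0)
      microhomology_length(reference, jx$donor_break[i],
                           jx$acceptor_break[i], jx$orientation[i], mh_max)
    }, numeric(1))
  } else if (nrow(jx)) {
    jx$mh_len <- ifelse(jx$consensus_insertion_len > 0, 0, jx$mh_len)
  }
  rownames(jx) <- NULL
  jx
}

#' Classify unique junctions as S-S or resected, productive or not
#'
#' A joint is resected when either coordinate falls outside its S region:
#' the donor break (half-open end of the donor segment) is inside the donor
#' S region iff the last donor base `donor_break - 1` is, and the acceptor
#' break is inside iff the coordinate itself is. `productive_length`
#' compares the coordinate-derived amplicon length
#' `(donor_break - primer5.start) + insertion + (primer3.end -
#' acceptor_break)` against the isotype's productive minimum.
#'
#' @param junctions Data frame from [dedup_and_filter()] (or any frame with
#'   `donor_break`, `acceptor_break`, optionally
#'   `consensus_insertion_len`).
#' @param locus A [locus_map()].
#' @return The input with `donor_out`, `acceptor_out`, `label`,
#'   `amplicon_len_coords`, `productive_length` columns added/recomputed.
#' @export
classify_joint <- function(junctions, locus) {
  dS <- locus$donor_S; aS <- locus$acceptor_S
  d <- junctions$donor_break; a <- junctions$acceptor_break
  ins <- junctions$consensus_insertion_len %||% rep(0, length(d))
  junctions$donor_out <- !(d > dS[1] & d <= dS[2])
  junctions$acceptor_out <- !(a >= aS[1] & a < aS[2])
  junctions$label <- ifelse(junctions$donor_out | junctions$acceptor_out,
                            "RESECTED", "S_S")
  junctions$amplicon_len_coords <-
    (d - locus$primer5[1]) + ins + (locus$primer3[2] - a)
  junctions$productive_length <- if (is.null(locus$thresholds)) NA else
    junctions$amplicon_len_coords > locus$thresholds$productive_min_len
  junctions
}

bin_counts <- function(x, lo, hi, bin_width) {
  nb <- ceiling((hi - lo) / bin_width)
  breaks <- lo + bin_width * (0:nb)
  x <- x[x >= lo & x < breaks[nb + 1]]
  ct <- tabulate(findInterval(x, breaks), nbins = nb)
  data.frame(bin_start = breaks[-(nb + 1)], bin_end = breaks[-1],
             count = ct)
}

#' Summarize an LR-PCR sequencing sample
#'
#' Median pass-ROI read length, percentage of pass-ROI reads at or below
#' the productive minimum (unproductive-length reads), percentage of
#' unique junctions classified resected, 250-bp-binned histograms of unique
#' junction coordinates over the donor and acceptor S regions +/- the ROI
#' pad, and the percentage of junction ends inside each S region.
#' Percentages are omitted (NULL), not reported as 0, when no reads or no
#' junctions contribute.
#'
#' @param read_lengths Lengths of pass-ROI reads (bp).
#' @param junctions Classified junction table from [classify_joint()].
#' @param locus A [locus_map()].
#' @param bin_width Histogram bin width in bp (default 250).
#' @param n_reads_in Optional total input read count (pre-filter).
#' @return A list of class `lrpcr_summary`.
#' @export
summarize_lrpcr <- function(read_lengths, junctions, locus,
                            bin_width = 250, n_reads_in = NULL) {
  out <- list(n_reads_in = n_reads_in %||% length(read_lengths),
              n_reads_pass_roi = length(read_lengths),
              n_unique_junctions = nrow(junctions),
              bin_width = bin_width)
  if (length(read_lengths)) {
    out$median_read_len <- stats::median(read_lengths)
    if (!is.null(locus$thresholds))
      out$pct_reads_below_productive_min <-
        100 * mean(read_lengths <= locus$thresholds$productive_min_len)
  }
  if (nrow(junctions)) {
    out$pct_unique_junctions_resected <-
      100 * mean(junctions$label == "RESECTED")
    out$pct_donor_in_S <- 100 * mean(!junctions$donor_out)
    out$pct_acceptor_in_S <- 100 * mean(!junctions$acceptor_out)
    out$donor_hist <- bin_counts(junctions$donor_break,
                                 locus$donor_S[1] - locus$roi_pad,
                                 locus$donor_S[2] + locus$roi_pad,
                                 bin_width)
    out$acceptor_hist <- bin_counts(junctions$acceptor_break,
                                    locus$acceptor_S[1] - locus$roi_pad,
                                    locus$acceptor_S[2] + locus$roi_pad,
                                    bin_width)
  }
  structure(out, class = "lrpcr_summary")
}

#' Run the full LR-PCR junction pipeline on reads
#'
#' Aligns reads (collapsing identical sequences first and carrying their
#' multiplicity as read support), applies the both-ends ROI filter,
#' extracts breakpoints, deduplicates to unique junctions at the depth
#' floor, classifies joints and summarizes the sample.
#'
#' @param reads Named character vector of read sequences, or a FASTQ path.
#' @param locus A [locus_map()].
#' @param reference Canonical reference sequence or a prebuilt
#'   [locus_index()].
#' @param min_depth Unique-junction depth floor (default 10).
#' @param bin_width Histogram bin width (default 250).
#' @param k Anchor length for the internal aligner.
#' @return List with `junctions` (classified unique junctions), `summary`
#'   (an `lrpcr_summary`), `calls` (per-distinct-read breakpoint calls) and
#'   `counts` (reads in / pass ROI / complex).
#' @export
lrpcr_pipeline <- function(reads, locus, reference, min_depth = 10,
                           bin_width = 250, k = 21) {
  if (length(reads) == 1 && is.null(names(reads)) && file.exists(reads)) {
    fq <- Biostrings::readDNAStringSet(reads, format = "fastq")
    reads <- stats::setNames(as.character(fq), names(fq))
  }
  index <- if (inherits(reference, "locus_index")) reference
           else locus_index(reference, k)
  useq <- unique(unname(reads))
  mult <- tabulate(match(reads, useq), nbins = length(useq))

  pass <- logical(length(useq))
  calls <- vector("list", length(useq))
  for (i in seq_along(useq)) {
    ch <- chain_align_read(useq[i], index, read_id = sprintf("u%06d", i))
    if (!roi_filter(ch, locus)) next
    pass[i] <- TRUE
    calls[[i]] <- extract_breakpoint(ch, locus, read = useq[i],
                                     reference = index$reference)
  }
  calls <- calls[pass]
  cdf <- breakpoint_calls_df(calls)
  n_complex_seqs <- attr(cdf, "n_complex")
  # attach multiplicities of the collapsed identical reads
  pass_ids <- sprintf("u%06d", which(pass))
  cdf$n_reads <- mult[match(cdf$read_id, pass_ids)]
  read_lengths <- rep(nchar(useq[pass]), mult[pass])

  jx <- dedup_and_filter(cdf, min_depth = min_depth, locus = locus,
                         reference = index$reference, rescue_tol = 100)
  jx <- classify_joint(jx, locus)
  summ <- summarize_lrpcr(read_lengths, jx, locus, bin_width = bin_width,
                          n_reads_in = length(reads))
  list(junctions = jx, summary = summ, calls = cdf,
       counts = c(n_reads_in = length(reads),
                  n_reads_pass_roi = length(read_lengths),
                  n_distinct_seqs = length(useq),
                  n_complex = n_complex_seqs))
}

#' Write unique junctions as BED (genome frame)
#'
#' Each junction contributes two single-base features (donor and acceptor
#' break) in 0-based half-open genome coordinates.
#'
#' @param junctions Junction table with `donor_break`, `acceptor_break`.
#' @param locus A [locus_map()].
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_junctions_bed <- function(junctions, locus, path) {
  if (!nrow(junctions)) { writeLines(character(0), path); return(invisible(path)) }
  g_d <- to_genome(locus, junctions$donor_break)
  g_a <- to_genome(locus, junctions$acceptor_break)
  df <- data.frame(
    chrom = locus$locus$chrom,
    start = c(g_d, g_a),
    end = c(g_d + 1, g_a + 1),
    name = c(sprintf("donor_%d", seq_len(nrow(junctions))),
             sprintf("acceptor_%d", seq_len(nrow(junctions)))))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
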