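# HTGTS-style junction-table analysis: read TLX-like tables, classify each
# junction by acceptor region and orientation, and compute the summary
# quantities of a switch-junction library (region fractions, INV/DEL ratio,
# resected fraction, binned distributions, repair-signature summaries).

TLX_MANDATORY <- c("read_id", "bait_chrom", "bait_coord", "bait_strand",
                   "prey_chrom", "prey_coord", "prey_strand")

#' Default TLX column dialect
#'
#' Maps the standard internal column names to the column names found in a
#' junction table. Override entries to consume other TLX flavors (e.g.
#' `list(read_id = "Qname", prey_chrom = "Rname", prey_coord = "Junction",
#' prey_strand = "Strand", ...)`).
#'
#' @return Named list mapping internal names to file column names.
#' @export
tlx_dialect_default <- function() {
  as.list(stats::setNames(c(TLX_MANDATORY, "junction_context"),
                          c(TLX_MANDATORY, "junction_context")))
}

#' Read a TLX-like junction table
#'
#' Parses a tab-separated junction table with a header row, mapping columns
#' through a dialect. Rows missing a mandatory field are dropped and
#' counted. Coordinates are kept in genome frame; conversion to canonical
#' coordinates happens at classification time.
#'
#' @param path TSV path.
#' @param dialect Named list as from [tlx_dialect_default()]; entries
#'   missing from the file header raise a configuration error.
#' @return Data frame of records with attribute `n_dropped`.
#' @export
read_tlx <- function(path, dialect = tlx_dialect_default()) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  missing_cols <- setdiff(unlist(dialect[TLX_MANDATORY]), names(raw))
  if (length(missing_cols))
    stopf("TLX dialect names columns absent from %s: %s", path,
          paste(missing_cols, collapse = ", "))
  df <- data.frame(
    read_id = as.character(raw[[dialect$read_id]]),
    bait_chrom = as.character(raw[[dialect$bait_chrom]]),
    bait_coord = suppressWarnings(as.numeric(raw[[dialect$bait_coord]])),
    bait_strand = as.character(raw[[dialect$bait_strand]]),
    prey_chrom = as.character(raw[[dialect$prey_chrom]]),
    prey_coord = suppressWarnings(as.numeric(raw[[dialect$prey_coord]])),
    prey_strand = as.character(raw[[dialect$prey_strand]]),
    stringsAsFactors = FALSE
  )
  ctx_col <- dialect$junction_context
  df$junction_context <-
    if (!is.null(ctx_col) && ctx_col %in% names(raw))
      as.character(raw[[ctx_col]]) else NA_character_
  ok <- !is.na(df$bait_coord) & !is.na(df$prey_coord) &
    nzchar(df$prey_chrom) & df$prey_strand %in% c("+", "-")
  out <- df[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!ok)
  out
}

# repair signature from a junction-context window: decompose the context
# against the donor- and acceptor-side templates (same machinery as the
# V(D)J decomposition); ambiguous overlap is MH, a gap is an insertion
context_signature <- function(context, reference, d, a, orientation, w) {
  t_d <- s_sub(reference, d - w, d + w)
  t_a <- if (orientation == "DEL") s_sub(reference, a - w, a + w)
         else rc_string(s_sub(reference, a - w, a + w))
  P <- anchored_prefix_len(context, t_d)
  Q <- anchored_prefix_len(rev_string(context), rev_string(t_a))
  o <- P + Q - nchar(context)
  list(mh_len = max(0L, o), ins_len = max(0L, -o))
}

#' Classify HTGTS junction records against a switch locus
#'
#' Assigns each prey to a region — intra-donor (`Smu_intra`, donor S region
#' +/- the ROI pad), acceptor (`Smu_acceptor`, acceptor S region +/- the
#' junction-pad assignment window), a named extra S region, `outside` (on
#' the locus but in none of the windows), or `translocation_other` (off the
#' locus chromosome/interval) — and each join as deletional (prey strand
#' equals the locus `del_strand`) or inversional. Acceptor joins whose prey
#' lies outside the unpadded acceptor S region are flagged resected. When
#' the reference (and optionally junction context) is available, per-join
#' repair signatures (MH / insertion) are computed.
#'
#' @param records Data frame from [read_tlx()] (genome-frame coordinates).
#' @param locus A [locus_map()].
#' @param reference Optional canonical reference sequence for signatures.
#' @param acceptor_window `"padded"` (default: acceptor S +/- junction_pad)
#'   or `"proper"` (unpadded) for the acceptor assignment.
#' @param context_width Context half-width used when junction contexts are
#'   present (default 40).
#' @return The records with `region`, `orientation`, `resected`, canonical
#'   `prey_cc`/`bait_cc`, and (when computable) `mh_len`, `ins_len` added.
#' @export
classify_record <- function(records, locus, reference = NULL,
                            acceptor_window = c("padded", "proper"),
                            context_width = 40) {
  acceptor_window <- match.arg(acceptor_window)
  n <- nrow(records)
  on_locus <- records$prey_chrom == locus$locus$chrom &
    records$prey_coord >= locus$locus$start &
    records$prey_coord < locus$locus$end
  prey_cc <- rep(NA_real_, n)
  prey_cc[on_locus] <- to_canonical(locus, records$prey_coord[on_locus])
  bait_on <- records$bait_chrom == locus$locus$chrom &
    records$bait_coord >= locus$locus$start &
    records$bait_coord < locus$locus$end
  bait_cc <- rep(NA_real_, n)
  bait_cc[bait_on] <- to_canonical(locus, records$bait_coord[bait_on])

  dwin <- c(locus$donor_S[1] - locus$roi_pad, locus$donor_S[2] + locus$roi_pad)
  awin <- if (acceptor_window == "padded")
    c(locus$acceptor_S[1] - locus$junction_pad,
      locus$acceptor_S[2] + locus$junction_pad)
  else locus$acceptor_S

  region <- rep("translocation_other", n)
  inw <- function(x, w) !is.na(x) & x >= w[1] & x < w[2]
  region[on_locus] <- "outside"
  region[inw(prey_cc, awin)] <- "Smu_acceptor"
  region[inw(prey_cc, dwin)] <- "Smu_intra"
  for (nm in names(locus$extra_S)) {
    xw <- c(locus$extra_S[[nm]][1] - locus$junction_pad,
            locus$extra_S[[nm]][2] + locus$junction_pad)
    sel <- inw(prey_cc, xw) & region == "outside"
    region[sel] <- nm
  }
  records$prey_cc <- prey_cc
  records$bait_cc <- bait_cc
  records$region <- region
  records$orientation <- ifelse(records$prey_strand == locus$del_strand,
                                "DEL", "INV")
  records$resected <- region == "Smu_acceptor" &
    !inw(prey_cc, locus$acceptor_S)

  if (!is.null(reference)) {
    mh <- rep(NA_real_, n); ins <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      if (is.na(prey_cc[i]) || is.na(bait_cc[i])) next
      ctx <- records$junction_context[i]
      if (!is.na(ctx) && nzchar(ctx)) {
        sig <- context_signature(ctx, reference, bait_cc[i], prey_cc[i],
                                 records$orientation[i], context_width)
        mh[i] <- sig$mh_len; ins[i] <- sig$ins_len
      } else {
        mh[i] <- microhomology_length(reference, bait_cc[i], prey_cc[i],
                                      records$orientation[i])
        ins[i] <- 0
      }
    }
    records$mh_len <- mh
    records$ins_len <- ins
  }
  records
}

#' Summarize a classified HTGTS junction set
#'
#' Region percentages over on-locus junctions, the inversional/deletional
#' ratio and resected fraction among acceptor (S-mu to acceptor-S) joins,
#' a genome-wide 1-kb-binned junction histogram across the locus, a
#' 250-bp-binned zoom over the acceptor assignment window, and a repair
#' signature summary over acceptor joins when signatures are present. The
#' INV/DEL ratio is omitted (NULL) when there are no deletional acceptor
#' joins.
#'
#' @param records Classified records from [classify_record()].
#' @param locus A [locus_map()].
#' @param genome_bin,zoom_bin Bin widths in bp (defaults 1000 and 250).
#' @return A list of class `htgts_summary`.
#' @export
summarize_htgts <- function(records, locus, genome_bin = 1000,
                            zoom_bin = 250) {
  on_locus <- records$region != "translocation_other"
  acc <- records$region == "Smu_acceptor"
  n_acc_del <- sum(acc & records$orientation == "DEL")
  n_acc_inv <- sum(acc & records$orientation == "INV")
  region_tab <- table(records$region[on_locus])
  out <- list(
    n_junctions = nrow(records),
    n_on_locus = sum(on_locus),
    pct_by_region = if (sum(on_locus))
      stats::setNames(as.numeric(100 * region_tab / sum(on_locus)),
                      names(region_tab)) else NULL,
    inv_del_ratio = if (n_acc_del > 0) n_acc_inv / n_acc_del else NULL,
    pct_resected_acceptor = if (sum(acc))
      100 * mean(records$resected[acc]) else NULL,
    genomewide_hist = bin_counts(records$prey_cc[on_locus], 0,
                                 locus_length(locus), genome_bin),
    zoom_hist = bin_counts(
      records$prey_cc[acc],
      max(0, locus$acceptor_S[1] - locus$junction_pad),
      min(locus_length(locus), locus$acceptor_S[2] + locus$junction_pad),
      zoom_bin)
  )
  if (!is.null(records$mh_len) && sum(acc & !is.na(records$mh_len)))
    out$signature <- signature_summary(
      data.frame(mh_len = records$mh_len[acc], ins_len = records$ins_len[acc]))
  structure(out, class = "htgts_summary")
}
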