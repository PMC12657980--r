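# Per-read alignment chains. Two routes produce the same `alignment_chain`
# structure: a built-in exact-seed chained aligner for synthetic amplicon
# reads (no external mapper needed at test time), and a SAM/BAM reader for
# real data mapped with a long-read mapper (minimap2 or similar). Blocks are
# in canonical locus coordinates, 0-based half-open, with read coordinates
# on the read as sequenced.
#
# The built-in aligner is deliberately not a general mapper: it assumes few
# (<= ~4) segments, low divergence (CCS-like), and unique k-mer anchors; a
# read k-mer hitting multiple reference positions is dropped rather than
# scored. Block ends are refined by maximal exact-match extension, which
# lands exactly on the junction-facing end (the donor-maximal placement of
# any microhomology tract) for error-free reads; isolated CCS errors near a
# junction perturb single reads only and are absorbed by the per-junction
# depth consensus.

DNA_CODE_MAX <- 3

dna_codes <- function(s) {
  x <- utf8ToInt(s)
  code <- rep(NA_integer_, 128)
  code[utf8ToInt("A")] <- 0L; code[utf8ToInt("C")] <- 1L
  code[utf8ToInt("G")] <- 2L; code[utf8ToInt("T")] <- 3L
  code[utf8ToInt("a")] <- 0L; code[utf8ToInt("c")] <- 1L
  code[utf8ToInt("g")] <- 2L; code[utf8ToInt("t")] <- 3L
  code[x]
}

# numeric value of every k-mer; entry i is the k-mer ENDING at position i
# (1-based), NA where the window contains a non-ACGT base. Exact for
# k <= 26 (values < 2^53).
kmer_values <- function(codes, k) {
  y <- stats::filter(codes, 4^((k - 1):0), method = "convolution", sides = 1)
  as.numeric(y)
}

#' Build a unique k-mer index of a locus reference
#'
#' Indexes both strands of the canonical reference; k-mers occurring more
#' than once across the two strands are discarded (switch-region repeats
#' make non-unique anchors uninformative).
#'
#' @param reference Canonical-strand reference sequence (character).
#' @param k Anchor length (odd, <= 26; default 21).
#' @return A `locus_index` used by [chain_align_read()].
#' @export
locus_index <- function(reference, k = 21) {
  L <- nchar(reference)
  if (L < k) stopf("reference shorter than anchor length k = %d", k)
  if (k > 26) stopf("anchor length k must be <= 26")
  n <- L - k + 1
  fwd <- kmer_values(dna_codes(reference), k)[k:L]
  rcv <- kmer_values(dna_codes(rc_string(reference)), k)[k:L]
  vals <- c(fwd, rcv)
  pos0 <- c(0:(n - 1), (L - k):0)                      # 0-based block start
  strand <- rep(c("+", "-"), each = n)
  keep <- !is.na(vals)
  vals <- vals[keep]; pos0 <- pos0[keep]; strand <- strand[keep]
  dup <- duplicated(vals) | duplicated(vals, fromLast = TRUE)
  vals <- vals[!dup]; pos0 <- pos0[!dup]; strand <- strand[!dup]
  o <- order(vals)
  structure(list(reference = reference, k = as.integer(k), L = L,
                 vals = vals[o], pos0 = pos0[o], strand = strand[o]),
            class = "locus_index")
}

# unique-anchor hits of `seq` against the index at the given query stride
collect_anchors <- function(index, seq, stride) {
  k <- index$k
  nc <- nchar(seq)
  if (nc < k) return(NULL)
  y <- kmer_values(dna_codes(seq), k)
  starts <- unique(c(seq(1L, nc - k + 1L, by = stride), nc - k + 1L))
  v <- y[starts + k - 1L]
  ok <- !is.na(v)
  starts <- starts[ok]; v <- v[ok]
  if (!length(v)) return(NULL)
  i <- findInterval(v, index$vals)
  hit <- i > 0 & index$vals[pmax(i, 1L)] == v
  if (!any(hit)) return(NULL)
  list(qpos0 = starts[hit] - 1L, rpos0 = index$pos0[i[hit]],
       strand = index$strand[i[hit]])
}

# maximal exact-match extension: length of the leading all-match run.
# Junction-facing block ends must not cross a single mismatch — switch
# repeats make donor and acceptor context locally similar, so any
# mismatch-tolerant extension overruns error-free junctions
# deterministically; isolated CCS errors near a junction perturb single
# reads only and are absorbed by the per-junction consensus vote.
exact_extend <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) return(0L)
  w <- min(nchar(a), nchar(b))
  m <- utf8ToInt(substr(a, 1, w)) == utf8ToInt(substr(b, 1, w))
  bad <- which(!m)
  if (!length(bad)) w else bad[1] - 1L
}

# interior divergence of an anchor group, estimated frame-true: anchors are
# merged into runs of constant diagonal (an indel shifts the diagonal and
# starts a new run) and read/reference substrings are compared within each
# run; transition zones between runs are excluded. Returns mismatches and
# the covered length.
group_mismatches <- function(read, ref, qg, rg, k, strand) {
  o <- order(qg); qg <- qg[o]; rg <- rg[o]
  dg <- if (strand == "+") rg - qg else rg + qg
  run <- cumsum(c(1L, diff(dg) != 0))
  mism <- 0L; covered <- 0L
  for (rid in unique(run)) {
    ix <- which(run == rid)
    f <- ix[1]; l <- ix[length(ix)]
    len <- qg[l] + k - qg[f]
    a <- s_sub(read, qg[f], qg[l] + k)
    b <- if (strand == "+") s_sub(ref, rg[f], rg[l] + k)
         else rc_string(s_sub(ref, rg[l], rg[f] + k))
    mism <- mism + sum(utf8ToInt(a) != utf8ToInt(b))
    covered <- covered + len
  }
  list(mism = mism, covered = covered)
}

#' Align one long read against a switch-locus reference
#'
#' Chains unique k-mer anchors into aligned blocks: anchors are grouped by
#' strand and (anti)diagonal within a band, each group is merged into a
#' block spanning its anchors, and block ends are refined by maximal
#' exact-match extension (junction-facing ends must not cross a mismatch;
#' see the package vignette). Blocks shorter than `min_block` on the read
#' or with interior mismatch fraction above `max_diverg` are discarded.
#' Intended for PacBio CCS amplicon reads with at most a few segments; real
#' data should come through [read_alignment_chains()].
#'
#' @param read Read sequence as sequenced (character).
#' @param reference Canonical-strand reference sequence, or a prebuilt
#'   [locus_index()] (recommended when aligning many reads).
#' @param k Anchor length when `reference` is a sequence.
#' @param max_diverg Post-hoc cap on the mismatch fraction tolerated within
#'   a block (blocks above `max_diverg` plus a 3-mismatch cushion are
#'   dropped).
#' @param min_block Minimum block length on the read (default 100 bp).
#' @param stride Query anchor sampling stride (default 13).
#' @param band Diagonal band for anchor grouping (default 32, absorbs small
#'   indels).
#' @param read_id Identifier stored in the chain.
#' @return An `alignment_chain`: list with `read_id`, `read_len`, and
#'   `blocks` (data frame `ref_start`, `ref_end`, `read_start`, `read_end`,
#'   `strand`, `matches`, sorted by `read_start`). Empty `blocks` when no
#'   anchor is found.
#' @export
chain_align_read <- function(read, reference, k = 21, max_diverg = 0.02,
                             min_block = 100, stride = 13, band = 32,
                             read_id = "read") {
  index <- if (inherits(reference, "locus_index")) reference
           else locus_index(reference, k)
  ref <- index$reference
  L <- index$L
  read_len <- nchar(read)
  if (read_len < 2 * index$k)
    stopf("read shorter than 2k (%d bp)", 2 * index$k)
  anc <- collect_anchors(index, read, stride)
  empty <- data.frame(ref_start = numeric(0), ref_end = numeric(0),
                      read_start = numeric(0), read_end = numeric(0),
                      strand = character(0), matches = numeric(0))
  chain <- structure(list(read_id = read_id, read_len = read_len,
                          blocks = empty),
                     class = "alignment_chain")
  if (is.null(anc)) return(chain)

  blocks <- list()
  for (st in c("+", "-")) {
    sel <- anc$strand == st
    if (!any(sel)) next
    q <- anc$qpos0[sel]; r <- anc$rpos0[sel]
    diagv <- if (st == "+") r - q else r + q
    o <- order(diagv, q)
    q <- q[o]; r <- r[o]; diagv <- diagv[o]
    grp <- cumsum(c(1L, diff(diagv) > band))
    for (g in unique(grp)) {
      gi <- which(grp == g)
      # a read k-mer spanning a junction can coincidentally match a unique
      # reference k-mer on a nearby diagonal; such chimeric anchors sit at
      # the block edges, so trim anchors deviating from the group's median
      # diagonal, then peel edge anchors whose diagonal jumps more than 5
      # from their neighbor (indel drift between adjacent anchors is +/- 1)
      dmed <- stats::median(diagv[gi])
      gi <- gi[abs(diagv[gi] - dmed) <= 16]
      if (!length(gi)) next
      gi <- gi[order(q[gi])]
      while (length(gi) >= 2 &&
             abs(diagv[gi[length(gi)]] - diagv[gi[length(gi) - 1]]) > 5)
        gi <- gi[-length(gi)]
      while (length(gi) >= 2 && abs(diagv[gi[1]] - diagv[gi[2]]) > 5)
        gi <- gi[-1]
      # block boundaries come from the extreme anchors as consistent
      # (read, ref) pairs
      i0 <- gi[which.min(q[gi])]; i1 <- gi[which.max(q[gi])]
      q0 <- q[i0]; q1 <- q[i1] + index$k
      dv <- group_mismatches(read, ref, q[gi], r[gi], index$k, st)
      if (st == "+") {
        r0 <- r[i0]; r1 <- r[i1] + index$k
        w <- min(400L, read_len - q1, L - r1)
        e <- exact_extend(s_sub(read, q1, q1 + w), s_sub(ref, r1, r1 + w))
        q1 <- q1 + e; r1 <- r1 + e
        w <- min(400L, q0, r0)
        e <- exact_extend(rev_string(s_sub(read, q0 - w, q0)),
                          rev_string(s_sub(ref, r0 - w, r0)))
        q0 <- q0 - e; r0 <- r0 - e
      } else {
        r0 <- r[i1]; r1 <- r[i0] + index$k
        # read right end pairs with ref left end and vice versa
        w <- min(400L, read_len - q1, r0)
        e <- exact_extend(s_sub(read, q1, q1 + w),
                          rc_string(s_sub(ref, r0 - w, r0)))
        q1 <- q1 + e; r0 <- r0 - e
        w <- min(400L, q0, L - r1)
        e <- exact_extend(rev_string(s_sub(read, q0 - w, q0)),
                          comp_string(s_sub(ref, r1, r1 + w)))
        q0 <- q0 - e; r1 <- r1 + e
      }
      span <- q1 - q0
      if (span < min_block) next
      if (dv$mism > max_diverg * dv$covered + 3) next
      blocks[[length(blocks) + 1L]] <-
        data.frame(ref_start = r0, ref_end = r1, read_start = q0,
                   read_end = q1, strand = st, matches = span - dv$mism)
    }
  }
  if (!length(blocks)) return(chain)
  bl <- do.call(rbind, blocks)
  bl <- bl[order(bl$read_start, bl$read_end), , drop = FALSE]
  rownames(bl) <- NULL
  chain$blocks <- bl
  chain
}

#' Both-ends region-of-interest filter
#'
#' A read is kept only if its alignment chain touches both sides of the
#' region of interest: at least one block overlapping the donor-side window
#' (`roi5_window`) and at least one overlapping the acceptor-side window
#' (`roi3_window`). Germline-only and single-ended reads are removed.
#'
#' @param chain An `alignment_chain` in canonical coordinates.
#' @param locus A [locus_map()].
#' @return `TRUE` iff the chain passes.
#' @export
roi_filter <- function(chain, locus) {
  bl <- chain$blocks
  if (!nrow(bl)) return(FALSE)
  ov <- function(win) any(bl$ref_start < win[2] & win[1] < bl$ref_end)
  ov(locus$roi5_window) && ov(locus$roi3_window)
}

parse_cigar <- function(cigar) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  if (!length(ops)) return(NULL)
  list(len = as.numeric(sub("[MIDNSHP=X]$", "", ops)),
       op = sub("^\\d+", "", ops))
}

#' Read per-read alignment chains from a SAM/BAM file
#'
#' Groups primary and supplementary records by read name, converts each
#' record's CIGAR to one aligned block (consuming soft/hard clips to
#' recover read coordinates on the read as sequenced), and maps genome
#' coordinates to canonical locus coordinates. Unmapped and secondary
#' records are ignored; records on other chromosomes or not fully inside
#' the locus interval are skipped and counted.
#'
#' @param path SAM or BAM file (SAM is converted on the fly).
#' @param locus A [locus_map()]; records must be aligned to a reference
#'   containing `locus$locus$chrom`.
#' @return List with `chains` (list of `alignment_chain`) and `skipped`
#'   (named counts of ignored records).
#' @export
read_alignment_chains <- function(path, locus) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest,
                             overwrite = TRUE, indexDestination = FALSE)
  }
  hdr <- Rsamtools::scanBamHeader(path)[[1]]$targets
  if (!(locus$locus$chrom %in% names(hdr)))
    stopf("sequence dictionary of %s lacks locus chrom '%s'",
          path, locus$locus$chrom)
  prm <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar"))
  rec <- Rsamtools::scanBam(path, param = prm)[[1]]
  n <- length(rec$qname)
  skipped <- c(unmapped = 0, secondary = 0, off_locus = 0)
  chains <- list()
  if (n == 0) return(list(chains = chains, skipped = skipped))

  per_read <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    fl <- rec$flag[i]
    if (bitwAnd(fl, 4L) != 0L) { skipped["unmapped"] <- skipped["unmapped"] + 1; next }
    if (bitwAnd(fl, 256L) != 0L) { skipped["secondary"] <- skipped["secondary"] + 1; next }
    if (as.character(rec$rname[i]) != locus$locus$chrom) {
      skipped["off_locus"] <- skipped["off_locus"] + 1; next
    }
    cg <- parse_cigar(rec$cigar[i])
    if (is.null(cg)) next
    ref_len <- sum(cg$len[cg$op %in% c("M", "D", "N", "=", "X")])
    q_aln <- sum(cg$len[cg$op %in% c("M", "I", "=", "X")])
    lead <- if (cg$op[1] %in% c("S", "H")) cg$len[1] else 0
    last <- length(cg$op)
    trail <- if (cg$op[last] %in% c("S", "H")) cg$len[last] else 0
    g0 <- rec$pos[i] - 1
    if (g0 < locus$locus$start || g0 + ref_len > locus$locus$end) {
      skipped["off_locus"] <- skipped["off_locus"] + 1; next
    }
    genome_strand <- if (bitwAnd(fl, 16L) != 0L) "-" else "+"
    read_start <- if (genome_strand == "-") trail else lead
    civ <- genome_interval_to_canonical(locus, c(g0, g0 + ref_len))
    cstrand <- if (genome_strand == locus$canonical_strand) "+" else "-"
    qn <- rec$qname[i]
    entry <- data.frame(ref_start = civ[1], ref_end = civ[2],
                        read_start = read_start,
                        read_end = read_start + q_aln,
                        strand = cstrand, matches = q_aln,
                        read_len = lead + q_aln + trail)
    per_read[[qn]] <- rbind(per_read[[qn]], entry)
  }
  for (qn in ls(per_read)) {
    bl <- per_read[[qn]]
    read_len <- max(bl$read_len)
    bl$read_len <- NULL
    bl <- bl[order(bl$read_start, bl$read_end), , drop = FALSE]
    rownames(bl) <- NULL
    chains[[qn]] <- structure(
      list(read_id = qn, read_len = read_len, blocks = bl),
      class = "alignment_chain")
  }
  list(chains = chains, skipped = skipped)
}

#' Write alignment chains as SAM (round-trip helper)
#'
#' Serializes chains to a minimal SAM file (primary record for the first
#' block of each read, supplementary records for the rest; sequences
#' omitted). Used to round-trip the internal aligner's output through the
#' standard-format reader.
#'
#' @param chains List of `alignment_chain` objects.
#' @param locus A [locus_map()].
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
write_chains_sam <- function(chains, locus, path) {
  con <- file(path, "w")
  on.exit(close(con))
  glen <- locus$locus$end
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               sprintf("@SQ\tSN:%s\tLN:%.0f", locus$locus$chrom, glen)), con)
  for (ch in chains) {
    bl <- ch$blocks
    for (i in seq_len(nrow(bl))) {
      giv <- canonical_interval_to_genome(locus,
                                          c(bl$ref_start[i], bl$ref_end[i]))
      genome_strand <- if ((bl$strand[i] == "+") ==
                           (locus$canonical_strand == "+")) "+" else "-"
      span <- bl$read_end[i] - bl$read_start[i]
      lead <- bl$read_start[i]
      trail <- ch$read_len - bl$read_end[i]
      if (genome_strand == "-") { tmp <- lead; lead <- trail; trail <- tmp }
      cig <- paste0(if (lead > 0) sprintf("%.0fS", lead) else "",
                    sprintf("%.0fM", span),
                    if (trail > 0) sprintf("%.0fS", trail) else "")
      flag <- (if (i > 1) 2048L else 0L) +
        (if (genome_strand == "-") 16L else 0L)
      writeLines(sprintf("%s\t%d\t%s\t%.0f\t60\t%s\t*\t0\t0\t*\t*",
                         ch$read_id, flag, locus$locus$chrom,
                         giv[1] + 1, cig), con)
    }
  }
  invisible(path)
}
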