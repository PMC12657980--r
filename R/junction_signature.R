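# Repair signatures at break junctions: microhomology (MH), untemplated
# insertions, direct joints, MH-usage landscapes, and decomposition of V(D)J
# Sanger junctions into resection / MH / insertion.
#
# MH convention used throughout the package: the microhomology of a junction
# (d, a) is the number of alternative placements of the junction within the
# joined sequence, i.e. the shared flank on either side of the stated break.
# A junction reported at the caller's canonical donor-maximal placement has
# all of its ambiguity on the 5' (donor) side, where this equals the usual
# "bases immediately 5' of the junction shared by both templates" definition.
# MH and untemplated insertion are mutually exclusive per junction: any
# untemplated base sets MH to 0.

# number of leading positions at which two equal-length strings agree
lead_match <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) return(0L)
  m <- utf8ToInt(a) == utf8ToInt(b)
  bad <- which(!m)
  if (!length(bad)) length(m) else bad[1] - 1L
}

rev_string <- function(s) {
  if (!nzchar(s)) return(s)
  intToUtf8(rev(utf8ToInt(s)))
}

comp_string <- function(s) chartr("ACGTacgt", "TGCAtgca", s)

# shared-flank lengths left/right of a junction (uncapped up to `win`)
mh_flanks <- function(reference, d, a, orientation = c("DEL", "INV"),
                      win = 50) {
  orientation <- match.arg(orientation)
  L <- s_len(reference)
  if (d < 0 || d > L || a < 0 || a > L)
    stopf("junction coordinates outside the reference")
  if (orientation == "DEL") {
    wl <- min(win, d, a)
    left <- lead_match(rev_string(s_sub(reference, d - wl, d)),
                       rev_string(s_sub(reference, a - wl, a)))
    wr <- min(win, L - d, L - a)
    right <- lead_match(s_sub(reference, d, d + wr),
                        s_sub(reference, a, a + wr))
  } else {
    # joined molecule is ref[..d) + revcomp(ref[..a)); alternative
    # placements are (d - i, a + i) on the left, (d + i, a - i) on the right
    wl <- min(win, d, L - a)
    left <- lead_match(rev_string(s_sub(reference, d - wl, d)),
                       comp_string(s_sub(reference, a, a + wl)))
    wr <- min(win, L - d, a)
    right <- lead_match(s_sub(reference, d, d + wr),
                        comp_string(rev_string(s_sub(reference, a - wr, a))))
  }
  list(left = left, right = right)
}

#' Microhomology length at a break junction
#'
#' Returns the length of the microhomology tract at the junction joining
#' the donor side ending at canonical coordinate `d` to the acceptor side
#' starting at `a` (deletional joins: joined molecule
#' `ref[..d) + ref[a..)`; inversional joins: `ref[..d) +
#' revcomp(ref[..a))`). The value equals the number of alternative
#' placements of the junction minus one, capped at `mh_max`; for a junction
#' reported at the donor-maximal placement it is exactly the longest `m`
#' with `ref[d-m..d) == ref[a-m..a)` (DEL) or
#' `ref[d-m..d) == revcomp(ref[a..a+m))` (INV). Windows truncated at the
#' sequence ends are compared over the available overlap only.
#'
#' @param reference Canonical-strand reference sequence (character).
#' @param d Donor break: canonical coordinate of the first base after the
#'   donor segment (0-based half-open end).
#' @param a Acceptor break: canonical coordinate of the first retained
#'   acceptor base (DEL) or of the half-open end of the inverted acceptor
#'   segment (INV).
#' @param orientation `"DEL"` or `"INV"`.
#' @param mh_max Cap on the reported MH length (default 20).
#' @return Integer MH length in `[0, mh_max]`.
#' @export
microhomology_length <- function(reference, d, a,
                                 orientation = c("DEL", "INV"),
                                 mh_max = 20) {
  fl <- mh_flanks(reference, d, a, orientation, win = mh_max)
  min(fl$left + fl$right, mh_max)
}

# Shift a junction to the canonical donor-maximal placement and report the
# MH there. Used by the simulator so truth tables carry the same coordinates
# the breakpoint caller reports.
canonical_junction <- function(reference, d, a,
                               orientation = c("DEL", "INV"),
                               mh_max = 20, win = 50) {
  orientation <- match.arg(orientation)
  fl <- mh_flanks(reference, d, a, orientation, win = win)
  r <- fl$right
  if (orientation == "DEL") {
    d2 <- d + r; a2 <- a + r
  } else {
    d2 <- d + r; a2 <- a - r
  }
  list(donor_break = d2, acceptor_break = a2,
       mh = min(fl$left + fl$right, mh_max))
}

#' Call the repair signature of one junction
#'
#' Implements the direct / microhomology / insertion partition: a junction
#' with untemplated read bases in the gap between the two aligned segments
#' is an insertion joint (MH set to 0 by convention); a gap-free junction
#' carries the microhomology implied by the reference context; a joint with
#' neither is a direct (blunt) joint.
#'
#' @param reference Canonical-strand reference sequence.
#' @param donor_break,acceptor_break Canonical junction coordinates.
#' @param orientation `"DEL"` or `"INV"`.
#' @param ins_len Length of the untemplated insertion (0 when none).
#' @param ins_seq Insertion sequence (optional, `""` when none).
#' @param mh_max Cap on MH length.
#' @return A list of class `junction_signature` with `mh_len`, `ins_len`,
#'   `ins_seq` and `direct`.
#' @export
call_signature <- function(reference, donor_break, acceptor_break,
                           orientation = "DEL", ins_len = 0, ins_seq = "",
                           mh_max = 20) {
  if (ins_len > 0) {
    mh <- 0L
  } else {
    if (is.null(reference) || !nzchar(reference))
      stopf("reference context required to compute microhomology")
    mh <- microhomology_length(reference, donor_break, acceptor_break,
                               orientation, mh_max)
  }
  structure(list(mh_len = as.integer(mh), ins_len = as.integer(ins_len),
                 ins_seq = if (ins_len > 0) ins_seq else "",
                 direct = (mh == 0L && ins_len == 0)),
            class = "junction_signature")
}

#' Summarize repair signatures over a set of junctions
#'
#' Computes the percentage of direct joints, of joints with microhomology
#' at least `mh_class_min` bp (the short-MH class diagnostic of Pol
#' theta-mediated end joining), of joints with insertions longer than 1 bp,
#' and the MH-usage landscape (fraction of all joints at each MH length
#' `0..mh_max`; insertion joints are tallied separately, so the landscape
#' sums to the direct-plus-MH fraction).
#'
#' @param signatures Data frame with columns `mh_len` and `ins_len` (one
#'   row per junction), or a list of [call_signature()] results.
#' @param mh_class_min MH class threshold in bp (default 4).
#' @param ins_class_min Insertion class threshold in bp (default 2,
#'   i.e. insertions > 1 bp).
#' @param mh_max Landscape axis maximum (default 20).
#' @return List with `n`, `pct_direct`, `pct_mh_ge_class`, `pct_ins_gt_1bp`,
#'   `pct_insertion`, and `landscape` (data frame `mh_len`, `fraction`).
#' @export
signature_summary <- function(signatures, mh_class_min = 4,
                              ins_class_min = 2, mh_max = 20) {
  if (is.data.frame(signatures)) {
    mh <- signatures$mh_len; ins <- signatures$ins_len
  } else {
    mh <- vapply(signatures, `[[`, numeric(1), "mh_len")
    ins <- vapply(signatures, `[[`, numeric(1), "ins_len")
  }
  n <- length(mh)
  if (n == 0) stopf("signature_summary: empty signature list")
  no_ins <- ins == 0
  landscape <- data.frame(
    mh_len = 0:mh_max,
    fraction = vapply(0:mh_max,
                      function(m) sum(no_ins & pmin(mh, mh_max) == m) / n,
                      numeric(1))
  )
  list(
    n = n,
    pct_direct = 100 * sum(no_ins & mh == 0) / n,
    pct_mh_ge_class = 100 * sum(no_ins & mh >= mh_class_min) / n,
    pct_ins_gt_1bp = 100 * sum(ins >= ins_class_min) / n,
    pct_insertion = 100 * sum(ins > 0) / n,
    landscape = landscape
  )
}

# longest prefix of `seq` matching the start of `ref` with <= max_mismatch
# mismatched positions (every position past the allowed mismatches must
# still be counted up to, not beyond, the (max_mismatch+1)-th mismatch)
anchored_prefix_len <- function(seq, ref, max_mismatch = 0) {
  w <- min(nchar(seq), nchar(ref))
  if (w == 0) return(0L)
  m <- utf8ToInt(substr(seq, 1, w)) == utf8ToInt(substr(ref, 1, w))
  bad <- which(!m)
  if (length(bad) <= max_mismatch) w else bad[max_mismatch + 1L] - 1L
}

#' Decompose a V(D)J Sanger junction into resection, MH and insertion
#'
#' Finds the longest prefix of `seq` matching the 5' end of the germline V
#' segment and the longest suffix matching the 3' end of the germline J
#' segment (each allowing up to `max_mismatch` mismatches). An overlap of
#' the two matched spans is microhomology; a gap is an untemplated
#' insertion. Placement ties inside an MH tract are broken at the
#' V-maximal (donor-maximal) split, mirroring the breakpoint caller's
#' convention, and resections are reported at that placement.
#'
#' @param seq Junction sequence (starts at the V 5' end, ends at the J 3'
#'   end; primer-anchored amplicon).
#' @param v_ref,j_ref Germline V and J reference sequences.
#' @param max_mismatch Mismatches tolerated in each anchored match
#'   (default 0; Sanger-quality sequence).
#' @return List of class `vdj_signature` with `v_resection`, `j_resection`,
#'   `mh_len`, `ins_len`, `ins_seq`.
#' @export
analyze_vdj_junction <- function(seq, v_ref, j_ref, max_mismatch = 0) {
  P <- anchored_prefix_len(seq, v_ref, max_mismatch)
  Q <- anchored_prefix_len(rev_string(seq), rev_string(j_ref), max_mismatch)
  if (P == 0 || Q == 0)
    stopf("junction sequence matches only one of the V/J references")
  n <- nchar(seq)
  o <- P + Q - n
  if (o > 0) {
    v_res <- nchar(v_ref) - P
    j_res <- nchar(j_ref) - (Q - o)
    mh <- o; ins_len <- 0L; ins_seq <- ""
  } else {
    v_res <- nchar(v_ref) - P
    j_res <- nchar(j_ref) - Q
    mh <- 0L
    ins_len <- -o
    ins_seq <- substr(seq, P + 1, P + ins_len)
  }
  structure(list(v_resection = as.integer(v_res),
                 j_resection = as.integer(j_res),
                 mh_len = as.integer(mh),
                 ins_len = as.integer(ins_len),
                 ins_seq = ins_seq),
            class = "vdj_signature")
}

#' Decompose a FASTA of V(D)J junction sequences
#'
#' Applies [analyze_vdj_junction()] to every record of a junction FASTA
#' against single-record V and J reference FASTAs.
#'
#' @param junction_fa,v_fa,j_fa Paths to FASTA files.
#' @param max_mismatch Passed to [analyze_vdj_junction()].
#' @return Data frame with one row per junction: `seq_id`, `v_resection`,
#'   `j_resection`, `mh_len`, `ins_len`, `ins_seq`.
#' @export
analyze_vdj_fasta <- function(junction_fa, v_fa, j_fa, max_mismatch = 0) {
  jx <- Biostrings::readDNAStringSet(junction_fa)
  v_ref <- as.character(Biostrings::readDNAStringSet(v_fa)[[1]])
  j_ref <- as.character(Biostrings::readDNAStringSet(j_fa)[[1]])
  res <- lapply(as.character(jx), analyze_vdj_junction,
                v_ref = v_ref, j_ref = j_ref, max_mismatch = max_mismatch)
  data.frame(
    seq_id = names(jx),
    v_resection = vapply(res, `[[`, integer(1), "v_resection"),
    j_resection = vapply(res, `[[`, integer(1), "j_resection"),
    mh_len = vapply(res, `[[`, integer(1), "mh_len"),
    ins_len = vapply(res, `[[`, integer(1), "ins_len"),
    ins_seq = vapply(res, `[[`, character(1), "ins_seq"),
    row.names = NULL
  )
}
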