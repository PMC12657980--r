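# Genomic model of one switch assay: primer footprints, donor/acceptor S
# regions, regions of interest and productive-length thresholds.
#
# Every coordinate stored in a `locus_map` is 0-based half-open on the
# canonical (transcriptional) strand of the locus, with 0 at the canonical
# 5' end. Genome-frame coordinates appear only at I/O boundaries
# (configuration files, SAM/BAM, TLX tables, BED output) and are converted
# with to_canonical()/to_genome(). This avoids strand/sign errors for loci
# such as Igh that sit on the genome minus strand.

#' Construct a switch-locus model
#'
#' A `locus_map` describes one long-range PCR / HTGTS switch assay: the
#' genomic interval of the locus, the two primer footprints, the donor
#' (S-mu) and acceptor (e.g. S-gamma1 or S-alpha) switch regions, optional
#' extra S regions, the regions of interest used for the both-ends read
#' filter, the HTGTS bait site, productive-amplicon length thresholds and a
#' junction blocklist (e.g. the rearranged non-productive CH12F3 allele).
#'
#' All interval arguments are length-2 numeric vectors `c(start, end)` in
#' canonical 0-based half-open coordinates (canonical 5' end of the locus at
#' 0). In canonical orientation `primer5` precedes `donor_S` precedes
#' `acceptor_S` precedes `primer3`.
#'
#' @param reference_name Sequence name of the canonical-strand reference the
#'   internal aligner and simulator use.
#' @param locus Genome-frame interval of the locus as
#'   `list(chrom=, start=, end=)`, 0-based half-open.
#' @param canonical_strand `"+"` or `"-"`: genome strand on which primer5
#'   precedes primer3 (transcriptional orientation of the locus).
#' @param primer5,primer3 Primer footprints (canonical coordinates).
#' @param donor_S,acceptor_S Donor and acceptor switch regions.
#' @param extra_S Named list of further S-region intervals (e.g. Sg3, Se).
#' @param roi_pad Pad (bp) added to each S region to build the regions of
#'   interest for the both-ends read filter. Default 5000.
#' @param junction_pad Pad (bp) around the acceptor S region within which an
#'   HTGTS prey is assigned to the acceptor (default 10000, the "+/- 10 kb"
#'   assignment window).
#' @param bait_site Canonical coordinate of the HTGTS bait primer 3' end.
#' @param bait_strand Strand of the bait primer on the canonical frame.
#' @param thresholds `list(productive_min_len=, productive_max_len=,
#'   label=)` in bp: amplicon-length window of productive S-S joins.
#' @param blocklist Data frame with columns `donor_break`, `acceptor_break`
#'   (canonical coordinates) of junction keys excluded from analysis.
#' @param del_strand Genome-frame prey strand that denotes a deletional
#'   HTGTS join for this bait design.
#' @param validate If `TRUE` (default) stop on any invariant violation.
#'
#' @return An object of class `locus_map`.
#' @seealso [validate_locus()], [load_locus_config()], [to_canonical()]
#' @export
locus_map <- function(reference_name,
                      locus,
                      canonical_strand = "+",
                      primer5,
                      primer3,
                      donor_S,
                      acceptor_S,
                      extra_S = list(),
                      roi_pad = 5000,
                      junction_pad = 10000,
                      bait_site = NULL,
                      bait_strand = "+",
                      thresholds = NULL,
                      blocklist = NULL,
                      del_strand = "+",
                      validate = TRUE) {
  locus_len <- locus$end - locus$start
  clip <- function(x) pmin(pmax(x, 0), locus_len)
  obj <- structure(list(
    reference_name = reference_name,
    locus = list(chrom = locus$chrom, start = as.numeric(locus$start),
                 end = as.numeric(locus$end)),
    canonical_strand = canonical_strand,
    primer5 = as.numeric(primer5),
    primer3 = as.numeric(primer3),
    donor_S = as.numeric(donor_S),
    acceptor_S = as.numeric(acceptor_S),
    extra_S = lapply(extra_S, as.numeric),
    roi_pad = as.numeric(roi_pad),
    junction_pad = as.numeric(junction_pad),
    roi5_window = clip(c(donor_S[1] - roi_pad, donor_S[2] + roi_pad)),
    roi3_window = clip(c(acceptor_S[1] - roi_pad, acceptor_S[2] + roi_pad)),
    bait_site = if (is.null(bait_site)) NULL else as.numeric(bait_site),
    bait_strand = bait_strand,
    thresholds = thresholds,
    blocklist = if (is.null(blocklist)) {
      data.frame(donor_break = numeric(0), acceptor_break = numeric(0))
    } else as.data.frame(blocklist),
    del_strand = del_strand
  ), class = "locus_map")
  if (validate) {
    v <- validate_locus(obj)
    if (length(v))
      stopf("invalid locus_map:\n%s", paste("-", v, collapse = "\n"))
  }
  obj
}

#' Length of the locus in bp
#' @param locus A `locus_map`.
#' @return Numeric length.
#' @export
locus_length <- function(locus) locus$locus$end - locus$locus$start

interval_ok <- function(iv) {
  length(iv) == 2 && !any(is.na(iv)) && iv[1] >= 0 && iv[1] < iv[2]
}

overlaps <- function(a, b) a[1] < b[2] && b[1] < a[2]

contains <- function(outer, inner) outer[1] <= inner[1] && inner[2] <= outer[2]

#' Validate a switch-locus model
#'
#' Checks every structural invariant of a [locus_map()] and reports the
#' violations instead of raising, so configuration errors can be listed in
#' one pass.
#'
#' @param locus A `locus_map`.
#' @return Character vector of violation descriptions; empty when the model
#'   is valid.
#' @export
validate_locus <- function(locus) {
  v <- character(0)
  add <- function(msg) v <<- c(v, msg)
  L <- locus_length(locus)
  if (is.null(locus$locus$chrom) || !nzchar(locus$locus$chrom))
    add("locus chrom must be non-empty")
  if (!(locus$canonical_strand %in% c("+", "-")))
    add("canonical_strand must be '+' or '-'")
  if (L <= 0) add("locus: start must be < end")
  for (nm in c("primer5", "primer3", "donor_S", "acceptor_S")) {
    if (!interval_ok(locus[[nm]])) add(sprintf("%s: malformed interval", nm))
  }
  if (length(v)) return(v)  # ordering checks need well-formed intervals

  ord <- c(locus$primer5[2], locus$donor_S[1], locus$donor_S[2],
           locus$acceptor_S[1], locus$acceptor_S[2], locus$primer3[1])
  if (is.unsorted(ord))
    add(paste("canonical ordering violated: require primer5.end <=",
              "donor_S <= acceptor_S <= primer3.start"))
  if (locus$primer3[2] > L)
    add("primer3 extends past the locus end")
  if (!contains(locus$roi5_window, locus$donor_S))
    add("roi5_window does not contain donor_S")
  if (!contains(locus$roi3_window, locus$acceptor_S))
    add("roi3_window does not contain acceptor_S")
  if (overlaps(locus$roi5_window, locus$roi3_window))
    add("roi5_window and roi3_window overlap; reduce roi_pad")
  if (!is.null(locus$bait_site) && locus$bait_site >= locus$donor_S[2])
    add("bait_site must lie within or upstream of donor_S")
  th <- locus$thresholds
  if (!is.null(th)) {
    if (!(th$productive_min_len > 0 &&
          th$productive_min_len < th$productive_max_len))
      add("thresholds: require 0 < productive_min_len < productive_max_len")
    germline <- locus$primer3[2] - locus$primer5[1]
    if (germline <= th$productive_max_len)
      add(paste("germline primer5-primer3 span must exceed",
                "thresholds.productive_max_len"))
  }
  bl <- locus$blocklist
  if (nrow(bl)) {
    bad <- bl$donor_break < 0 | bl$donor_break > L |
      bl$acceptor_break < 0 | bl$acceptor_break > L
    if (any(bad))
      add(sprintf("blocklist: %d entr%s outside the locus",
                  sum(bad), if (sum(bad) == 1) "y" else "ies"))
  }
  for (nm in names(locus$extra_S)) {
    if (!interval_ok(locus$extra_S[[nm]]))
      add(sprintf("extra_S[%s]: malformed interval", nm))
  }
  v
}

#' Convert genome coordinates to canonical locus coordinates
#'
#' The canonical frame is 0-based with 0 at the canonical 5' end of the
#' locus; for a minus-strand locus the map is order-reversing
#' (`(end - 1) - g`), so downstream-in-transcription is always increasing.
#'
#' @param locus A `locus_map`.
#' @param g Genome coordinates (0-based), within the locus interval.
#' @return Canonical coordinates (numeric vector).
#' @export
to_canonical <- function(locus, g) {
  if (any(g < locus$locus$start | g >= locus$locus$end))
    stopf("coordinate outside locus [%.0f, %.0f)",
          locus$locus$start, locus$locus$end)
  if (locus$canonical_strand == "+") g - locus$locus$start
  else (locus$locus$end - 1) - g
}

#' Convert canonical locus coordinates back to genome coordinates
#'
#' Inverse of [to_canonical()].
#'
#' @param locus A `locus_map`.
#' @param cc Canonical coordinates in `[0, locus_length)`.
#' @return Genome coordinates.
#' @export
to_genome <- function(locus, cc) {
  L <- locus_length(locus)
  if (any(cc < 0 | cc >= L))
    stopf("canonical coordinate outside [0, %.0f)", L)
  if (locus$canonical_strand == "+") locus$locus$start + cc
  else (locus$locus$end - 1) - cc
}

# genome-frame half-open interval for a canonical half-open interval;
# break coordinates are junction boundaries, so intervals convert as
# [start,end) -> on '-' loci [end' , start') with end' = locus.end - end
canonical_interval_to_genome <- function(locus, iv) {
  if (locus$canonical_strand == "+") {
    c(locus$locus$start + iv[1], locus$locus$start + iv[2])
  } else {
    c(locus$locus$end - iv[2], locus$locus$end - iv[1])
  }
}

genome_interval_to_canonical <- function(locus, iv) {
  if (locus$canonical_strand == "+") {
    c(iv[1] - locus$locus$start, iv[2] - locus$locus$start)
  } else {
    c(locus$locus$end - iv[2], locus$locus$end - iv[1])
  }
}

#' Load a switch-locus configuration file
#'
#' Reads a YAML locus configuration and returns a validated [locus_map()]
#' normalized to internal canonical 0-based half-open coordinates. The file
#' must declare its coordinate convention explicitly
#' (`coord_convention: 0-based-half-open` or `1-based-inclusive`); intervals
#' are given in genome frame as `[start, end]`.
#'
#' Expected keys: `reference`, `locus` (`chrom`, `start`, `end`), `strand`,
#' `coord_convention`, `primer5`, `primer3`, `s_regions` (named; must
#' include `donor` and `acceptor`), `roi_pad`, `junction_pad`, `bait_site`
#' (`coord`, `strand`), `thresholds` (`productive_min_kb`,
#' `productive_max_kb`, `label`), `del_strand`, `blocklist` (list of
#' `[donor_break, acceptor_break]` genome-frame pairs).
#'
#' @param path Path to a YAML file.
#' @return A validated `locus_map`.
#' @export
load_locus_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  need <- function(key) {
    if (is.null(cfg[[key]])) stopf("config key missing: %s", key)
    cfg[[key]]
  }
  conv <- need("coord_convention")
  if (!(conv %in% c("0-based-half-open", "1-based-inclusive")))
    stopf("config key 'coord_convention' must be '0-based-half-open' or '1-based-inclusive', got '%s'",
          conv)
  # normalize a genome interval to 0-based half-open
  norm_iv <- function(iv, key) {
    iv <- unlist(iv)
    if (length(iv) != 2 || any(is.na(suppressWarnings(as.numeric(iv)))))
      stopf("config key '%s': expected a numeric [start, end] pair", key)
    iv <- as.numeric(iv)
    if (conv == "1-based-inclusive") iv <- c(iv[1] - 1, iv[2])
    iv
  }
  loc <- need("locus")
  loc_iv <- norm_iv(c(loc$start, loc$end), "locus")
  loc <- list(chrom = loc$chrom, start = loc_iv[1], end = loc_iv[2])
  strand <- need("strand")
  stub <- list(locus = loc, canonical_strand = strand)
  g2c_iv <- function(iv) genome_interval_to_canonical(stub, iv)

  sreg <- need("s_regions")
  if (is.null(sreg$donor) || is.null(sreg$acceptor))
    stopf("config key 's_regions' must name 'donor' and 'acceptor'")
  extra_names <- setdiff(names(sreg), c("donor", "acceptor"))
  extra <- lapply(sreg[extra_names], function(x) g2c_iv(norm_iv(x, "s_regions")))

  th <- cfg$thresholds
  thresholds <- if (is.null(th)) NULL else list(
    productive_min_len = th$productive_min_kb * 1000,
    productive_max_len = th$productive_max_kb * 1000,
    label = th$label %||% "isotype"
  )
  bl <- cfg$blocklist
  blocklist <- if (is.null(bl) || !length(bl)) NULL else {
    pairs <- lapply(bl, function(p) {
      p <- as.numeric(unlist(p))
      if (length(p) != 2) stopf("config key 'blocklist': entries must be pairs")
      c(to_canonical(stub, p[1]), to_canonical(stub, p[2]))
    })
    data.frame(donor_break = vapply(pairs, `[`, numeric(1), 1),
               acceptor_break = vapply(pairs, `[`, numeric(1), 2))
  }
  bait <- cfg$bait_site
  bait_coord <- NULL
  bait_strand <- "+"
  if (!is.null(bait)) {
    bait_coord <- to_canonical(stub, as.numeric(bait$coord) -
                                 (conv == "1-based-inclusive"))
    bait_strand <- if (strand == "+") bait$strand %||% "+" else {
      if ((bait$strand %||% "+") == "+") "-" else "+"
    }
  }
  lm <- locus_map(
    reference_name = need("reference"),
    locus = loc,
    canonical_strand = strand,
    primer5 = g2c_iv(norm_iv(need("primer5"), "primer5")),
    primer3 = g2c_iv(norm_iv(need("primer3"), "primer3")),
    donor_S = g2c_iv(norm_iv(sreg$donor, "s_regions.donor")),
    acceptor_S = g2c_iv(norm_iv(sreg$acceptor, "s_regions.acceptor")),
    extra_S = extra,
    roi_pad = cfg$roi_pad %||% 5000,
    junction_pad = cfg$junction_pad %||% 10000,
    bait_site = bait_coord,
    bait_strand = bait_strand,
    thresholds = thresholds,
    blocklist = blocklist,
    del_strand = cfg$del_strand %||% "+",
    validate = FALSE
  )
  v <- validate_locus(lm)
  if (length(v))
    stopf("locus config %s fails validation:\n%s",
          path, paste("-", v, collapse = "\n"))
  lm
}

#' Write a switch-locus configuration file
#'
#' Serializes a [locus_map()] to YAML in genome frame, 0-based half-open.
#' `load_locus_config(write_locus_config(x, path))` reproduces `x`.
#'
#' @param locus A `locus_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_locus_config <- function(locus, path) {
  c2g_iv <- function(iv) canonical_interval_to_genome(locus, iv)
  sreg <- c(list(donor = c2g_iv(locus$donor_S),
                 acceptor = c2g_iv(locus$acceptor_S)),
            lapply(locus$extra_S, c2g_iv))
  cfg <- list(
    reference = locus$reference_name,
    coord_convention = "0-based-half-open",
    locus = list(chrom = locus$locus$chrom, start = locus$locus$start,
                 end = locus$locus$end),
    strand = locus$canonical_strand,
    primer5 = c2g_iv(locus$primer5),
    primer3 = c2g_iv(locus$primer3),
    s_regions = sreg,
    roi_pad = locus$roi_pad,
    junction_pad = locus$junction_pad,
    del_strand = locus$del_strand
  )
  if (!is.null(locus$bait_site)) {
    cfg$bait_site <- list(
      coord = to_genome(locus, locus$bait_site),
      strand = if (locus$canonical_strand == "+") locus$bait_strand
               else if (locus$bait_strand == "+") "-" else "+"
    )
  }
  if (!is.null(locus$thresholds)) {
    cfg$thresholds <- list(
      productive_min_kb = locus$thresholds$productive_min_len / 1000,
      productive_max_kb = locus$thresholds$productive_max_len / 1000,
      label = locus$thresholds$label
    )
  }
  if (nrow(locus$blocklist)) {
    cfg$blocklist <- lapply(seq_len(nrow(locus$blocklist)), function(i) {
      c(to_genome(locus, locus$blocklist$donor_break[i]),
        to_genome(locus, locus$blocklist$acceptor_break[i]))
    })
  }
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @export
print.locus_map <- function(x, ...) {
  cat(sprintf("locus_map: %s (%s:%.0f-%.0f, canonical strand %s)\n",
              x$reference_name, x$locus$chrom, x$locus$start, x$locus$end,
              x$canonical_strand))
  cat(sprintf("  donor_S    [%.0f, %.0f)   acceptor_S [%.0f, %.0f)\n",
              x$donor_S[1], x$donor_S[2], x$acceptor_S[1], x$acceptor_S[2]))
  cat(sprintf("  roi5 [%.0f, %.0f)  roi3 [%.0f, %.0f)  junction_pad %.0f\n",
              x$roi5_window[1], x$roi5_window[2],
              x$roi3_window[1], x$roi3_window[2], x$junction_pad))
  if (!is.null(x$thresholds))
    cat(sprintf("  productive amplicon: %.1f-%.1f kb (%s)\n",
                x$thresholds$productive_min_len / 1000,
                x$thresholds$productive_max_len / 1000,
                x$thresholds$label %||% ""))
  invisible(x)
}
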