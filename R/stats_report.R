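# Metaphase-aberration contingency statistics (two-sided Fisher's exact
# contrasts) and the consolidated run orchestrator.

#' Two-sided Fisher's exact test p-value for a 2x2 table
#'
#' Probability-mass method: with both margins fixed, the p-value is the sum
#' of hypergeometric probabilities of every table whose probability does
#' not exceed that of the observed table (relative tie tolerance 1e-12).
#' This is the standard two-sided rule for genotype-vs-outcome contrasts of
#' metaphase counts.
#'
#' @param a,b,c,d Cell counts of the table `rbind(c(a, b), c(c, d))`.
#' @return The p-value in (0, 1].
#' @export
fisher_exact_two_sided <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts)))
    stopf("counts must be non-negative integers")
  if (sum(counts) == 0)
    stopf("Fisher's exact test undefined for an all-zero table")
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  x <- lo:hi
  probs <- stats::dhyper(x, r1, r2, c1)
  p_obs <- probs[x == a]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}

#' Percentages and Fisher contrasts for metaphase aberration tables
#'
#' For each group reports the percentage of aberrant metaphases (breaks
#' plus translocations; a metaphase is counted in at most one class), of
#' metaphases with breaks, and of metaphases with translocations. Each
#' non-reference group is compared to the reference with three two-sided
#' Fisher's exact tests: normal vs aberrant, break vs others, and
#' translocation vs others.
#'
#' @param tables Data frame with columns `group_id`, `n_total`, `n_breaks`,
#'   `n_translocations` (one row per group; disjoint counts).
#' @param reference_group `group_id` of the reference (e.g. `"WT"`).
#' @return List with `percentages` (data frame) and `tests` (data frame of
#'   p-values per non-reference group).
#' @export
aberration_report <- function(tables, reference_group) {
  req <- c("group_id", "n_total", "n_breaks", "n_translocations")
  missing_cols <- setdiff(req, names(tables))
  if (length(missing_cols))
    stopf("missing columns: %s", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(tables$group_id))
    stopf("duplicate group_id in metaphase tables")
  if (!(reference_group %in% tables$group_id))
    stopf("reference group '%s' not present", reference_group)
  ab <- tables$n_breaks + tables$n_translocations
  if (any(ab > tables$n_total))
    stopf("n_breaks + n_translocations exceeds n_total")
  pct <- data.frame(
    group_id = tables$group_id,
    n_total = tables$n_total,
    pct_aberrant = 100 * ab / tables$n_total,
    pct_breaks = 100 * tables$n_breaks / tables$n_total,
    pct_translocations = 100 * tables$n_translocations / tables$n_total
  )
  ref <- tables[tables$group_id == reference_group, ]
  ref_ab <- ref$n_breaks + ref$n_translocations
  others <- tables[tables$group_id != reference_group, , drop = FALSE]
  tests <- do.call(rbind, lapply(seq_len(nrow(others)), function(i) {
    g <- others[i, ]
    g_ab <- g$n_breaks + g$n_translocations
    data.frame(
      group_id = g$group_id,
      reference = reference_group,
      p_normal_vs_aberrant = fisher_exact_two_sided(
        ref$n_total - ref_ab, ref_ab, g$n_total - g_ab, g_ab),
      p_break_vs_others = fisher_exact_two_sided(
        ref$n_breaks, ref$n_total - ref$n_breaks,
        g$n_breaks, g$n_total - g$n_breaks),
      p_translocation_vs_others = fisher_exact_two_sided(
        ref$n_translocations, ref$n_total - ref$n_translocations,
        g$n_translocations, g$n_total - g$n_translocations)
    )
  }))
  if (is.null(tests))
    tests <- data.frame(group_id = character(0), reference = character(0),
                        p_normal_vs_aberrant = numeric(0),
                        p_break_vs_others = numeric(0),
                        p_translocation_vs_others = numeric(0))
  list(percentages = pct, tests = tests)
}

summary_to_json <- function(x) {
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, dataframe = "columns",
                   null = "null", pretty = TRUE)
}

#' Run a complete analysis mode and write its report bundle
#'
#' Orchestrates the package's modules behind one entry point. `config` is a
#' list (or path to a YAML file) with `mode` one of `simulate`, `lrpcr`,
#' `htgts`, `vdj`, `metaphase`, an output directory `out`, and mode
#' specific inputs:
#' \describe{
#'   \item{simulate}{`sim`: arguments for [sim_params()]. Writes the locus
#'     config, reference FASTA, LR-PCR FASTQ, truth table CSV, HTGTS TSV
#'     and V(D)J FASTA/truth files.}
#'   \item{lrpcr}{`locus_config`, `reads` (FASTQ) + `reference` (FASTA) or
#'     `bam`, optional `min_depth`, `bin`. Writes the unique-junction TSV,
#'     histograms, BED and a JSON summary.}
#'   \item{htgts}{`locus_config`, `tlx`, optional `reference`. Writes the
#'     classified junction TSV, histograms, BED and JSON summary.}
#'   \item{vdj}{`junctions` (FASTA), `v_ref`, `j_ref`. Writes the signature
#'     TSV and JSON summary.}
#'   \item{metaphase}{`counts` (CSV), `reference_group`. Writes percentage
#'     and test TSVs and a JSON report.}
#' }
#' A `run_log.json` with mode, seed, parameters and package version is
#' written alongside every bundle.
#'
#' @param config List or YAML path as described above.
#' @return Invisibly, a named list of the written file paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  mode <- config$mode %||% stopf("config must name a mode")
  out_dir <- config$out %||% stopf("config must name an output directory 'out'")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  emit <- function(name, path) { paths[[name]] <<- path; path }

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  }

  if (mode == "simulate") {
    params <- do.call(sim_params, config$sim %||% list())
    sim <- stage("locus", make_synthetic_locus(params))
    events <- stage("events", sample_events(params, sim$locus, sim$reference))
    rd <- stage("reads", render_lrpcr_reads(events, sim$reference,
                                            sim$locus, params))
    tlx <- stage("htgts", render_htgts_table(events, sim$reference,
                                             sim$locus, params))
    vdj <- stage("vdj", render_vdj_junctions(params))
    write_locus_config(sim$locus, emit("locus_config",
                                       file.path(out_dir, "locus.yaml")))
    Biostrings::writeXStringSet(
      stats::setNames(Biostrings::DNAStringSet(sim$reference),
                      sim$locus$reference_name),
      emit("reference", file.path(out_dir, "reference.fa")))
    write_reads_fastq(rd$reads, emit("reads", file.path(out_dir, "reads.fastq")))
    utils::write.csv(events, emit("truth", file.path(out_dir, "truth.csv")),
                     row.names = FALSE)
    write_tsv(tlx, emit("tlx", file.path(out_dir, "htgts.tsv")))
    Biostrings::writeXStringSet(
      stats::setNames(Biostrings::DNAStringSet(vdj$v_ref), "V_segment"),
      emit("v_ref", file.path(out_dir, "vdj_v.fa")))
    Biostrings::writeXStringSet(
      stats::setNames(Biostrings::DNAStringSet(vdj$j_ref), "J_segment"),
      emit("j_ref", file.path(out_dir, "vdj_j.fa")))
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(vdj$junctions),
      emit("vdj_junctions", file.path(out_dir, "vdj_junctions.fa")))
    utils::write.csv(vdj$truth,
                     emit("vdj_truth", file.path(out_dir, "vdj_truth.csv")),
                     row.names = FALSE)
    log_params <- unclass(params)
  } else if (mode == "lrpcr") {
    locus <- stage("locus", load_locus_config(config$locus_config))
    min_depth <- config$min_depth %||% 10
    bin <- config$bin %||% 250
    if (!is.null(config$bam)) {
      rc <- stage("bam", read_alignment_chains(config$bam, locus))
      calls <- list(); lens <- numeric(0)
      for (ch in rc$chains) {
        if (!roi_filter(ch, locus)) next
        calls[[length(calls) + 1]] <- extract_breakpoint(ch, locus)
        lens <- c(lens, ch$read_len)
      }
      cdf <- breakpoint_calls_df(calls)
      jx <- dedup_and_filter(cdf, min_depth = min_depth, locus = locus)
      jx <- classify_joint(jx, locus)
      res <- list(junctions = jx,
                  summary = summarize_lrpcr(lens, jx, locus, bin),
                  counts = c(n_records = length(rc$chains)))
    } else {
      reference <- as.character(
        Biostrings::readDNAStringSet(config$reference)[[1]])
      res <- stage("lrpcr", lrpcr_pipeline(config$reads, locus, reference,
                                           min_depth = min_depth,
                                           bin_width = bin))
    }
    jx_out <- res$junctions
    if (nrow(jx_out)) {
      jx_out$donor_break_genome <- to_genome(locus, jx_out$donor_break)
      jx_out$acceptor_break_genome <- to_genome(locus, jx_out$acceptor_break)
    }
    write_tsv(jx_out, emit("junctions", file.path(out_dir, "junctions.tsv")))
    write_junctions_bed(res$junctions, locus,
                        emit("bed", file.path(out_dir, "junctions.bed")))
    s <- res$summary
    if (!is.null(s$donor_hist))
      write_tsv(s$donor_hist, emit("donor_hist",
                                   file.path(out_dir, "donor_hist.tsv")))
    if (!is.null(s$acceptor_hist))
      write_tsv(s$acceptor_hist,
                emit("acceptor_hist", file.path(out_dir, "acceptor_hist.tsv")))
    s$donor_hist <- NULL; s$acceptor_hist <- NULL
    writeLines(summary_to_json(unclass(s)),
               emit("summary", file.path(out_dir, "summary.json")))
    log_params <- list(min_depth = min_depth, bin = bin)
  } else if (mode == "htgts") {
    locus <- stage("locus", load_locus_config(config$locus_config))
    reference <- if (is.null(config$reference)) NULL else
      as.character(Biostrings::readDNAStringSet(config$reference)[[1]])
    rec <- stage("tlx", read_tlx(config$tlx))
    cls <- stage("classify", classify_record(rec, locus, reference))
    s <- stage("summary", summarize_htgts(cls, locus))
    write_tsv(cls, emit("classified", file.path(out_dir, "classified.tsv")))
    write_tsv(s$genomewide_hist,
              emit("genomewide_hist",
                   file.path(out_dir, "genomewide_hist.tsv")))
    write_tsv(s$zoom_hist, emit("zoom_hist",
                                file.path(out_dir, "zoom_hist.tsv")))
    s$genomewide_hist <- NULL; s$zoom_hist <- NULL
    if (!is.null(s$signature)) {
      write_tsv(s$signature$landscape,
                emit("mh_landscape", file.path(out_dir, "mh_landscape.tsv")))
      s$signature$landscape <- NULL
    }
    writeLines(summary_to_json(unclass(s)),
               emit("summary", file.path(out_dir, "summary.json")))
    log_params <- list(tlx = config$tlx)
  } else if (mode == "vdj") {
    sig <- stage("vdj", analyze_vdj_fasta(config$junctions, config$v_ref,
                                          config$j_ref,
                                          config$max_mismatch %||% 0))
    write_tsv(sig, emit("signatures",
                        file.path(out_dir, "vdj_signatures.tsv")))
    summ <- list(
      n = nrow(sig),
      mean_v_resection = mean(sig$v_resection),
      mean_j_resection = mean(sig$j_resection),
      pct_with_mh = 100 * mean(sig$mh_len > 0),
      pct_with_insertion = 100 * mean(sig$ins_len > 0)
    )
    writeLines(summary_to_json(summ),
               emit("summary", file.path(out_dir, "vdj_summary.json")))
    log_params <- list(max_mismatch = config$max_mismatch %||% 0)
  } else if (mode == "metaphase") {
    counts <- stage("counts",
                    utils::read.csv(config$counts, stringsAsFactors = FALSE))
    rep <- stage("report",
                 aberration_report(counts, config$reference_group))
    write_tsv(rep$percentages,
              emit("percentages", file.path(out_dir, "percentages.tsv")))
    write_tsv(rep$tests, emit("tests", file.path(out_dir, "fisher_tests.tsv")))
    writeLines(summary_to_json(rep),
               emit("summary", file.path(out_dir, "metaphase_report.json")))
    log_params <- list(reference_group = config$reference_group)
  } else {
    stopf("unknown mode '%s'", mode)
  }

  log <- list(mode = mode,
              package = "switchjoint",
              version = as.character(utils::packageVersion("switchjoint")),
              seed = config$sim$seed %||% config$seed %||% NA,
              params = log_params)
  writeLines(summary_to_json(log),
             emit("run_log", file.path(out_dir, "run_log.json")))
  invisible(paths)
}
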