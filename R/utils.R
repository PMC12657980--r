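# Internal helpers shared across modules. All genomic arithmetic inside the
# package uses 0-based half-open coordinates on the canonical (transcriptional)
# strand of a locus; these helpers keep the 0-based <-> R 1-based conversion in
# one place.

#' @importFrom Biostrings DNAString DNAStringSet reverseComplement
#'   writeXStringSet readDNAStringSet
NULL

# substring of `s` over 0-based half-open [start, end)
s_sub <- function(s, start, end) {
  if (end <= start) return("")
  substr(s, start + 1L, end)
}

s_len <- nchar

rc_string <- function(s) {
  if (!nzchar(s)) return(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# vectorized single-character comparison of two equal-length strings
str_eq_vec <- function(a, b) {
  utf8ToInt(a) == utf8ToInt(b)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# geometric tract length >= 1 with mean `mean_len` (mean_len > 1)
rgeom_tract <- function(n, mean_len, cap = Inf) {
  p <- 1 / max(mean_len, 1 + 1e-9)
  t <- 1L + stats::rgeom(n, prob = p)
  pmin(t, cap)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, stringsAsFactors = FALSE, ...)
}
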