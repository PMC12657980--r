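# Independent oracles used across the suite. They deliberately share no
# code path with the package implementation they check.

# 0-based half-open substring, local copy for oracle independence
o_sub <- function(s, start, end) if (end <= start) "" else substr(s, start + 1, end)

o_rc <- function(s) {
  if (!nzchar(s)) return(s)
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# Brute-force microhomology oracle: enumerate every placement of the joined
# sequence window against the two templates and count the valid ones.
mh_oracle <- function(reference, d, a, orientation = "DEL", mh_max = 20,
                      W = 30) {
  if (orientation == "DEL") {
    joined <- paste0(o_sub(reference, d - W, d), o_sub(reference, a, a + W))
    valid <- vapply(-W:W, function(i) {
      alt <- paste0(o_sub(reference, d - W, d + i),
                    o_sub(reference, a + i, a + W))
      nchar(alt) == 2 * W && alt == joined
    }, logical(1))
  } else {
    joined <- paste0(o_sub(reference, d - W, d),
                     o_rc(o_sub(reference, a - W, a)))
    valid <- vapply(-W:W, function(i) {
      alt <- paste0(o_sub(reference, d - W, d + i),
                    o_rc(o_sub(reference, a - W, a - i)))
      nchar(alt) == 2 * W && alt == joined
    }, logical(1))
  }
  min(sum(valid) - 1L, mh_max)
}

# Exact-rational two-sided Fisher oracle: hypergeometric probabilities from
# binomial coefficients (exact in doubles for totals <= 40).
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  x <- max(0, c1 - r2):min(r1, c1)
  num <- choose(r1, x) * choose(r2, c1 - x)
  p_obs <- num[x == a]
  sum(num[num <= p_obs]) / choose(r1 + r2, c1)
}

# Brute-force V(D)J decomposition: enumerate all (split, gap) decompositions
# of `seq` into a V prefix, an untemplated gap, and a J suffix; return the
# V-maximal one, with MH = number of gap-free splits minus one when the
# canonical decomposition is gap-free.
vdj_oracle <- function(seq, v_ref, j_ref) {
  n <- nchar(seq)
  pref_ok <- vapply(0:min(n, nchar(v_ref)), function(x)
    x == 0 || substr(seq, 1, x) == substr(v_ref, 1, x), logical(1))
  x_ok <- (0:min(n, nchar(v_ref)))[pref_ok]
  suff_ok <- vapply(0:min(n, nchar(j_ref)), function(y)
    y == 0 || substr(seq, n - y + 1, n) ==
      substr(j_ref, nchar(j_ref) - y + 1, nchar(j_ref)), logical(1))
  y_ok <- (0:min(n, nchar(j_ref)))[suff_ok]
  P <- max(x_ok); Q <- max(y_ok)
  o <- P + Q - n
  if (o > 0) {
    # gap-free splits s satisfy: prefix s matches and suffix n - s matches
    splits <- x_ok[x_ok %in% (n - y_ok)]
    s <- max(splits)
    list(v_resection = nchar(v_ref) - s,
         j_resection = nchar(j_ref) - (n - s),
         mh_len = length(splits) - 1L, ins_len = 0L)
  } else {
    list(v_resection = nchar(v_ref) - P,
         j_resection = nchar(j_ref) - Q,
         mh_len = 0L, ins_len = n - P - Q)
  }
}

rnd_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                             collapse = "")
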