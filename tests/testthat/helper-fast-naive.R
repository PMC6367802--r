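# A second, vectorized-but-still-naive IUPAC matcher used where the fully
# positionwise oracle would be too slow: per motif offset j it AND-combines
# set membership of the shifted character vector.  No regex, no package
# scanning code.

naive_iupac_count_vec_one <- function(chars, pattern) {
  pat <- strsplit(pattern, "")[[1]]
  w <- length(pat)
  L <- length(chars)
  if (L < w) return(0L)
  P <- L - w + 1L
  valid <- rep(TRUE, P)
  for (j in seq_len(w))
    valid <- valid & chars[j:(j + P - 1L)] %in% IUPAC_SETS[[pat[j]]]
  sum(valid)
}

naive_iupac_count_vec <- function(seq, iupac, both_strands = TRUE) {
  chars <- strsplit(seq, "")[[1]]
  n <- naive_iupac_count_vec_one(chars, iupac)
  if (both_strands) {
    rc <- naive_revcomp(iupac)
    if (rc != iupac) n <- n + naive_iupac_count_vec_one(chars, rc)
  }
  n
}

# random IUPAC consensus for scan-equivalence checks
random_iupac_motif <- function(min_len = 4, max_len = 10,
                               degeneracy = 0.2) {
  len <- sample(min_len:max_len, 1)
  paste(vapply(seq_len(len), function(.) {
    if (runif(1) < degeneracy)
      sample(c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N"), 1)
    else sample(c("A", "C", "G", "T"), 1)
  }, character(1)), collapse = "")
}
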