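# Independent oracles shared across test files.  These re-derive expected
# values by the most literal route available (plain loops, direct formula
# evaluation) and never call the code paths they check.

# Best-close-match categories by exhaustive scanning.
bcm_oracle <- function(mat, species, threshold, tie_tol = 1e-12) {
  out <- character(nrow(mat))
  for (q in seq_len(nrow(mat))) {
    best <- Inf
    hits <- character(0)
    for (j in seq_len(nrow(mat))) {
      if (j == q || is.na(mat[q, j])) next
      if (mat[q, j] < best) best <- mat[q, j]
    }
    if (!is.finite(best)) { out[q] <- "uncomparable"; next }
    for (j in seq_len(nrow(mat))) {
      if (j == q || is.na(mat[q, j])) next
      if (mat[q, j] <= best + tie_tol) hits <- union(hits, species[j])
    }
    out[q] <- if (best > threshold) "no_id"
      else if (identical(hits, species[q])) "correct"
      else if (species[q] %in% hits) "ambiguous"
      else "incorrect"
  }
  out
}

# One-line K2P evaluation from two aligned strings: tally transition and
# transversion columns directly, then apply the Kimura (1980) formula.
k2p_oracle <- function(a, b) {
  va <- strsplit(a, "")[[1]]
  vb <- strsplit(b, "")[[1]]
  ok <- va %in% c("A", "C", "G", "T") & vb %in% c("A", "C", "G", "T")
  va <- va[ok]; vb <- vb[ok]
  if (!length(va)) return(NA_real_)
  purine <- c("A", "G")
  ts <- sum(va != vb & ((va %in% purine) == (vb %in% purine)))
  tv <- sum(va != vb) - ts
  P <- ts / length(va); Q <- tv / length(va)
  if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0) return(NA_real_)
  -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
}
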