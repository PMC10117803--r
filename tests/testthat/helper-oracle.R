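# Independent pure-R affine-gap local-alignment oracle (plain Gotoh
# recurrences over full matrices, no optimizations). Written against the
# scoring definition only; kept independent of the package's C++ kernel.
oracle_sw_score <- function(q, t, scheme) {
  mat <- scheme$matrix
  go <- scheme$gap_open
  ge <- scheme$gap_extend
  qc <- strsplit(q, "")[[1]]
  tc <- strsplit(t, "")[[1]]
  n <- length(qc)
  m <- length(tc)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n) + 1) {
    for (j in seq_len(m) + 1) {
      E[i, j] <- max(H[i, j - 1] - go - ge, E[i, j - 1] - ge)
      F[i, j] <- max(H[i - 1, j] - go - ge, F[i - 1, j] - ge)
      H[i, j] <- max(0, H[i - 1, j - 1] + mat[qc[i - 1], tc[j - 1]],
                     E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# random peptide over the 20 standard residues (local to tests)
rand_pep <- function(n) {
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
               n, replace = TRUE), collapse = "")
}
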