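# independent permutation enumerator (iterative insertion, distinct from the
# package's recursive implementation)
perms_oracle <- function(n) {
  out <- matrix(1L, 1, 1)
  for (m in 2:n) {
    k <- nrow(out)
    grown <- matrix(0L, k * m, m)
    for (pos in seq_len(m)) {
      rows <- (pos - 1L) * k + seq_len(k)
      grown[rows, ] <- cbind(out[, seq_len(pos - 1L), drop = FALSE], m,
                             out[, seq(pos, m - 1L)[seq_len(m - pos)],
                                 drop = FALSE])
    }
    out <- grown
  }
  out
}
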