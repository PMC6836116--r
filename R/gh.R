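# Gauss-Hermite nodes/weights (weight function exp(-x^2)) by Golub-Welsch:
# eigen-decomposition of the symmetric tridiagonal Jacobi matrix. n is small
# (<= ~25), so a dense eigen() is fine.
gauss_hermite <- function(n) {
  stopifnot(n >= 1, n == round(n))
  if (n == 1) return(list(nodes = 0, weights = sqrt(pi)))
  J <- matrix(0, n, n)
  off <- sqrt(seq_len(n - 1) / 2)
  J[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- off
  J[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord],
       weights = sqrt(pi) * e$vectors[1, ord]^2)
}
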