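# Independent oracles used across the suite. These deliberately avoid the
# package's own evaluation/quadrature code paths.

# Cox-de Boor recursion, one basis function at a time.
deboor_basis <- function(knots, j, ord, x) {
  n <- length(knots) - 1
  # order-1 indicators; closed at the global right endpoint
  Bprev <- vapply(seq_len(n), function(i) {
    as.numeric(x >= knots[i] & (x < knots[i + 1] |
      (x == knots[length(knots)] & knots[i + 1] == knots[length(knots)])))
  }, numeric(length(x)))
  Bprev <- matrix(Bprev, nrow = length(x))
  if (ord == 1) return(Bprev[, j])
  for (k in 2:ord) {
    ncols <- n - k + 1
    Bcur <- matrix(0, length(x), ncols)
    for (i in seq_len(ncols)) {
      d1 <- knots[i + k - 1] - knots[i]
      d2 <- knots[i + k] - knots[i + 1]
      t1 <- if (d1 > 0) (x - knots[i]) / d1 * Bprev[, i] else 0
      t2 <- if (d2 > 0) (knots[i + k] - x) / d2 * Bprev[, i + 1] else 0
      Bcur[, i] <- t1 + t2
    }
    Bprev <- Bcur
  }
  Bprev[, j]
}

deboor_design <- function(basis, x) {
  vapply(seq_len(basis$dimension), function(j)
    deboor_basis(basis$knots, j, basis$order, x), numeric(length(x)))
}

# Dense midpoint-Riemann integral of f over [a, b].
riemann <- function(f, a, b, n = 20000) {
  h <- (b - a) / n
  x <- a + (seq_len(n) - 0.5) * h
  sum(f(x)) * h
}

riemann_gram <- function(basis, basis2 = basis, n = 20000) {
  a <- basis$domain[1]; b <- basis$domain[2]
  h <- (b - a) / n
  x <- a + (seq_len(n) - 0.5) * h
  B1 <- eval_basis(basis, x)
  B2 <- eval_basis(basis2, x)
  t(B1) %*% B2 * h
}

rmse_brute <- function(p, o) sqrt(sum((p - o)^2) / length(p))
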