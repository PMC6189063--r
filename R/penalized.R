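# Penalized least-squares core shared by the functional regressions and the
# ridge-penalized DLNM baseline.
#
# Minimizes ||y - X theta||^2 + sum_j lambda_j * theta' P_j theta, where each
# P_j is a full-size (p x p) penalty embedding that is zero outside its block.
# Smoothing parameters are chosen by generalized cross-validation
#   GCV(lambda) = n * RSS / (n - edf)^2,   edf = tr((X'X + P)^{-1} X'X),
# over a logarithmic grid; each grid is rescaled by tr(X'X)/tr(P_j) restricted
# to the penalized block, so grids are dimensionless.

pls_fit <- function(X, y, penalties = list(), lambda = "gcv",
                    lambda_grid = 10^seq(-8, 8, length.out = 33),
                    n_eff = NULL) {
  n <- length(y)
  n_gcv <- if (is.null(n_eff)) n else n_eff
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  yty <- sum(y^2)

  if (length(penalties) == 0) {
    theta <- solve(XtX, Xty)
    fitted <- drop(X %*% theta)
    return(list(coef = drop(theta), fitted = fitted, lambda = numeric(0),
                edf = ncol(X), gcv = NA_real_,
                solver = function(ynew) drop(solve(XtX, crossprod(X, ynew)))))
  }

  # dimensionless scale per penalty block
  scales <- vapply(penalties, function(P) {
    act <- which(diag(P) > 0 | rowSums(abs(P)) > 0)
    s <- sum(diag(XtX)[act]) / sum(diag(P)[act])
    if (!is.finite(s) || s <= 0) 1 else s
  }, numeric(1))

  solve_at <- function(lam) {
    Ptot <- Reduce(`+`, Map(function(P, l) l * P, penalties, as.list(lam)))
    M <- XtX + Ptot
    theta <- solve(M, Xty)
    rss <- max(yty - 2 * sum(theta * Xty) + drop(crossprod(theta, XtX %*% theta)), 0)
    edf <- sum(diag(solve(M, XtX)))
    list(theta = theta, rss = rss, edf = edf, M = M,
         gcv = if (edf >= n_gcv) Inf else n_gcv * rss / (n_gcv - edf)^2)
  }

  if (is.numeric(lambda)) {
    if (length(lambda) != length(penalties))
      stop("'lambda' must supply one value per penalty")
    best_lam <- lambda
    best <- solve_at(best_lam)
  } else {
    grids <- lapply(scales, function(s) lambda_grid * s)
    combos <- as.matrix(expand.grid(grids, KEEP.OUT.ATTRS = FALSE))
    gcvs <- apply(combos, 1, function(lam) solve_at(lam)$gcv)
    best_lam <- combos[which.min(gcvs), ]
    best <- solve_at(best_lam)
  }

  M <- best$M
  list(coef = drop(best$theta), fitted = drop(X %*% best$theta),
       lambda = as.numeric(best_lam), edf = best$edf, gcv = best$gcv,
       solver = function(ynew) drop(solve(M, crossprod(X, ynew))))
}

# Embed a block penalty matrix into a p x p zero matrix at columns `cols`.
embed_penalty <- function(P_block, p, cols) {
  P <- matrix(0, p, p)
  P[cols, cols] <- P_block
  P
}
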