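#' B-spline basis system on a closed interval
#'
#' Constructs a B-spline basis with equally spaced interior knots on
#' \code{domain}. The basis dimension is \code{n_interior_knots + order};
#' boundary knots are replicated to full multiplicity so the basis spans
#' the closed interval and forms a partition of unity everywhere on it.
#'
#' @param domain numeric length-2 vector \code{c(lower, upper)}, in the
#'   units of the problem (hours for daily curves, days for annual curves).
#' @param n_interior_knots number of equally spaced interior knots
#'   (\code{>= 0}).
#' @param order spline order (polynomial degree + 1); the default 4 gives
#'   cubic splines.
#' @return An object of class \code{fd_basis} with elements \code{domain},
#'   \code{order}, \code{interior_knots}, \code{knots} (full knot vector
#'   with boundary multiplicity) and \code{dimension}.
#' @examples
#' b <- fd_basis(c(0, 24), n_interior_knots = 10)
#' b$dimension  # 14
#' @export
fd_basis <- function(domain, n_interior_knots, order = 4L) {
  if (length(domain) != 2L || !all(is.finite(domain)))
    stop("'domain' must be two finite numbers c(lower, upper)")
  if (domain[2] <= domain[1])
    stop("'domain' upper bound must exceed the lower bound")
  if (!is.finite(order) || order < 1)
    stop("'order' must be a positive integer (>= 1)")
  if (!is.finite(n_interior_knots) || n_interior_knots < 0)
    stop("'n_interior_knots' must be a non-negative integer")
  order <- as.integer(order)
  n_interior_knots <- as.integer(n_interior_knots)
  h <- diff(domain) / (n_interior_knots + 1)
  interior <- if (n_interior_knots > 0)
    domain[1] + h * seq_len(n_interior_knots) else numeric(0)
  structure(
    list(domain = as.numeric(domain),
         order = order,
         interior_knots = interior,
         knots = c(rep(domain[1], order), interior, rep(domain[2], order)),
         dimension = n_interior_knots + order),
    class = "fd_basis")
}

#' B-spline basis with explicitly placed interior knots
#'
#' Like \code{\link{fd_basis}} but with a caller-supplied interior knot
#' vector (used e.g. for percentile-placed temperature knots and
#' log-spaced lag knots in the DLNM cross-basis).
#'
#' @param domain numeric length-2 vector.
#' @param interior_knots sorted knots strictly inside the domain.
#' @param order spline order (default 4 = cubic).
#' @return An \code{fd_basis}.
#' @export
fd_basis_knots <- function(domain, interior_knots, order = 4L) {
  b <- fd_basis(domain, 0L, order)
  interior_knots <- sort(as.numeric(interior_knots))
  if (length(interior_knots) &&
      (min(interior_knots) <= domain[1] || max(interior_knots) >= domain[2]))
    stop("'interior_knots' must lie strictly inside the domain")
  b$interior_knots <- interior_knots
  b$knots <- c(rep(domain[1], order), interior_knots, rep(domain[2], order))
  b$dimension <- length(interior_knots) + b$order
  b
}

#' @export
print.fd_basis <- function(x, ...) {
  cat(sprintf("B-spline basis on [%g, %g]: order %d, %d interior knots, dimension %d\n",
              x$domain[1], x$domain[2], x$order,
              length(x$interior_knots), x$dimension))
  invisible(x)
}

same_basis <- function(a, b) {
  isTRUE(all.equal(a$domain, b$domain)) && a$order == b$order &&
    isTRUE(all.equal(a$interior_knots, b$interior_knots))
}

#' Evaluate the basis functions (or a derivative) on a grid
#'
#' @param basis an \code{fd_basis}.
#' @param x evaluation points, all inside the closed domain (no
#'   extrapolation).
#' @param deriv derivative order (0 = function values).
#' @return \code{length(x) x dimension} matrix of basis values.
#' @export
eval_basis <- function(basis, x, deriv = 0L) {
  stopifnot(inherits(basis, "fd_basis"))
  if (any(!is.finite(x)))
    stop("evaluation points must be finite")
  if (any(x < basis$domain[1] - 1e-10 | x > basis$domain[2] + 1e-10))
    stop(sprintf("evaluation points outside the basis domain [%g, %g]; no extrapolation",
                 basis$domain[1], basis$domain[2]))
  x <- pmin(pmax(x, basis$domain[1]), basis$domain[2])
  splines::splineDesign(basis$knots, x, ord = basis$order,
                        derivs = rep(as.integer(deriv), length(x)))
}

#' A sample of curves sharing one basis
#'
#' Thin container for functional data: \code{n} curves represented by an
#' \code{n x dimension} coefficient matrix over a shared \code{fd_basis}.
#'
#' @param basis an \code{fd_basis}.
#' @param coefs numeric matrix (\code{n_curves x dimension}) of basis
#'   coefficients, one row per curve.
#' @param labels optional curve identifiers (dates, years, ...).
#' @return An object of class \code{fd_sample}.
#' @export
fd_sample <- function(basis, coefs, labels = NULL) {
  stopifnot(inherits(basis, "fd_basis"))
  coefs <- as.matrix(coefs)
  if (ncol(coefs) != basis$dimension)
    stop(sprintf("coefficient matrix has %d columns but the basis dimension is %d",
                 ncol(coefs), basis$dimension))
  if (!is.null(labels) && length(labels) != nrow(coefs))
    stop("'labels' length must equal the number of curves")
  structure(list(basis = basis, coefs = coefs, labels = labels),
            class = "fd_sample")
}

#' @export
print.fd_sample <- function(x, ...) {
  cat(sprintf("Functional sample: %d curve(s) on [%g, %g], basis dimension %d\n",
              nrow(x$coefs), x$basis$domain[1], x$basis$domain[2],
              x$basis$dimension))
  invisible(x)
}

#' Evaluate every curve of a functional sample on a grid
#'
#' @param sample an \code{fd_sample}.
#' @param grid evaluation points inside the domain.
#' @return \code{n_curves x length(grid)} matrix of curve values.
#' @export
eval_fd <- function(sample, grid) {
  stopifnot(inherits(sample, "fd_sample"))
  B <- eval_basis(sample$basis, grid)
  out <- sample$coefs %*% t(B)
  rownames(out) <- sample$labels
  out
}

#' Smooth discrete measurements into functional data
#'
#' Per-curve ordinary least-squares projection of (position, value)
#' measurements onto the span of \code{basis}: the residual sum of squares
#' is minimal over that span, so measurements generated exactly from a
#' member of the span are reproduced. Missing values inside a curve are
#' allowed; a curve with fewer usable points than the basis dimension is
#' an error.
#'
#' @param measurements either a list of per-curve data frames/matrices with
#'   columns (position, value), or a single numeric matrix of values
#'   (\code{n_curves x n_points}) together with \code{positions}, when all
#'   curves share one measurement grid.
#' @param basis an \code{fd_basis}.
#' @param positions shared measurement grid (used with the matrix form).
#' @param labels optional curve identifiers.
#' @return An \code{fd_sample} of fitted curves.
#' @export
fd_smooth <- function(measurements, basis, positions = NULL, labels = NULL) {
  stopifnot(inherits(basis, "fd_basis"))
  if (is.matrix(measurements) || (is.numeric(measurements) && !is.null(positions))) {
    Y <- if (is.matrix(measurements)) measurements else matrix(measurements, nrow = 1)
    if (is.null(positions) || length(positions) != ncol(Y))
      stop("'positions' must match the number of measurement columns")
    if (!anyNA(Y)) {
      if (length(positions) < basis$dimension)
        stop("fewer measurement points than basis dimension")
      B <- eval_basis(basis, positions)
      qrB <- qr(B)
      if (qrB$rank < basis$dimension)
        stop("rank-deficient smoothing design: measurement positions do not identify the basis")
      coefs <- t(qr.coef(qrB, t(Y)))
      return(fd_sample(basis, coefs, labels))
    }
    measurements <- lapply(seq_len(nrow(Y)), function(i) {
      ok <- !is.na(Y[i, ])
      cbind(positions[ok], Y[i, ok])
    })
  }
  if (!is.list(measurements))
    stop("'measurements' must be a matrix (with 'positions') or a list of (position, value) tables")
  if (is.null(labels)) labels <- names(measurements)
  coefs <- matrix(NA_real_, length(measurements), basis$dimension)
  for (i in seq_along(measurements)) {
    m <- as.matrix(measurements[[i]])
    m <- m[stats::complete.cases(m), , drop = FALSE]
    lab <- if (!is.null(labels)) labels[i] else i
    if (nrow(m) < basis$dimension)
      stop(sprintf("curve '%s' has %d points but the basis dimension is %d",
                   lab, nrow(m), basis$dimension))
    B <- eval_basis(basis, m[, 1])
    qrB <- qr(B)
    if (qrB$rank < basis$dimension)
      stop(sprintf("rank-deficient smoothing design for curve '%s'", lab))
    coefs[i, ] <- qr.coef(qrB, m[, 2])
  }
  fd_sample(basis, coefs, labels)
}

#' Choose the number of equally spaced knots by leave-one-out CV
#'
#' For each candidate interior-knot count, every curve is smoothed by
#' least squares and the leave-one-out cross-validation score is the mean,
#' over all measurement points of all curves, of the squared error made
#' when predicting each point from a fit that excludes it. The score is
#' computed with the hat-matrix identity
#' \eqn{e_{(l)} = e_l / (1 - h_{ll})}, which equals brute-force refitting.
#' Ties are broken toward fewer knots.
#'
#' @param measurements as in \code{\link{fd_smooth}}.
#' @param domain,order passed to \code{\link{fd_basis}}.
#' @param candidate_knot_counts integer vector of interior-knot counts to
#'   score; every candidate must be feasible (basis dimension at most the
#'   smallest per-curve point count).
#' @param positions shared grid (matrix form of \code{measurements}).
#' @return list with \code{best_count} and a data frame \code{cv_scores}
#'   (columns \code{n_knots}, \code{score}).
#' @export
select_knots_loocv <- function(measurements, domain, order = 4L,
                               candidate_knot_counts, positions = NULL) {
  if (length(candidate_knot_counts) == 0)
    stop("'candidate_knot_counts' must not be empty")
  curves <- normalize_measurements(measurements, positions)
  min_pts <- min(vapply(curves, nrow, 1L))
  scores <- vapply(candidate_knot_counts, function(nk) {
    basis <- fd_basis(domain, nk, order)
    if (basis$dimension > min_pts)
      stop(sprintf("candidate with %d knots needs %d points per curve but the smallest curve has %d",
                   nk, basis$dimension, min_pts))
    sse <- 0; npts <- 0
    for (m in curves) {
      B <- eval_basis(basis, m[, 1])
      qrB <- qr(B)
      e <- qr.resid(qrB, m[, 2])
      h <- rowSums(qr.Q(qrB)[, seq_len(qrB$rank), drop = FALSE]^2)
      sse <- sse + sum((e / (1 - h))^2)
      npts <- npts + nrow(m)
    }
    sse / npts
  }, numeric(1))
  ord <- order(scores, candidate_knot_counts)  # ties -> fewer knots
  list(best_count = candidate_knot_counts[ord[1]],
       cv_scores = data.frame(n_knots = candidate_knot_counts, score = scores))
}

normalize_measurements <- function(measurements, positions = NULL) {
  if (is.matrix(measurements)) {
    if (is.null(positions) || length(positions) != ncol(measurements))
      stop("'positions' must match the number of measurement columns")
    return(lapply(seq_len(nrow(measurements)), function(i) {
      ok <- !is.na(measurements[i, ])
      cbind(positions[ok], measurements[i, ok])
    }))
  }
  lapply(measurements, function(m) {
    m <- as.matrix(m)
    m[stats::complete.cases(m), , drop = FALSE]
  })
}

# Gauss-Legendre nodes/weights per knot span; exact for products of basis
# functions (degree <= 2*(order-1), order+1 nodes integrate degree
# 2*order+1).
gl_rule <- function(breaks, n_nodes) {
  ref <- pracma::gaussLegendre(n_nodes, 0, 1)
  nodes <- weights <- numeric(0)
  for (i in seq_len(length(breaks) - 1)) {
    a <- breaks[i]; b <- breaks[i + 1]
    if (b - a <= 0) next
    nodes <- c(nodes, a + (b - a) * ref$x)
    weights <- c(weights, (b - a) * ref$w)
  }
  list(x = nodes, w = weights)
}

span_breaks <- function(basis) {
  unique(c(basis$domain[1], basis$interior_knots, basis$domain[2]))
}

#' Gram matrix of one basis, or cross-Gram of two bases
#'
#' Entry (j, k) is \eqn{\int b_j(u) c_k(u) du} over the common domain,
#' computed by Gauss-Legendre quadrature per knot span (polynomial-exact,
#' so the integrals are not a tolerance source). With one argument the
#' result is the symmetric positive semi-definite Gram matrix of the basis.
#'
#' @param basis an \code{fd_basis}.
#' @param basis2 optional second \code{fd_basis} on the same domain.
#' @return \code{dim(basis) x dim(basis2)} matrix of pairwise integrals.
#' @export
gram_matrix <- function(basis, basis2 = basis) {
  stopifnot(inherits(basis, "fd_basis"), inherits(basis2, "fd_basis"))
  if (!isTRUE(all.equal(basis$domain, basis2$domain)))
    stop("bases must share the same domain")
  breaks <- sort(unique(c(span_breaks(basis), span_breaks(basis2))))
  rule <- gl_rule(breaks, max(basis$order, basis2$order) + 1L)
  B1 <- eval_basis(basis, rule$x)
  B2 <- eval_basis(basis2, rule$x)
  G <- t(B1) %*% (rule$w * B2)
  if (same_basis(basis, basis2)) G <- (G + t(G)) / 2
  G
}

#' Inner product of two curves
#'
#' \eqn{\int f(u) g(u) du} computed in coefficient space through the Gram
#' matrix of the shared basis. Both curves must live on the same basis.
#'
#' @param f,g \code{fd_sample}s with a single curve each (or equal curve
#'   counts, in which case inner products are computed pairwise by row).
#' @return numeric vector of inner products.
#' @export
inner_product <- function(f, g) {
  stopifnot(inherits(f, "fd_sample"), inherits(g, "fd_sample"))
  if (!same_basis(f$basis, g$basis))
    stop("curves live on different bases; project onto a common basis first")
  if (nrow(f$coefs) != nrow(g$coefs))
    stop("curve counts differ")
  G <- gram_matrix(f$basis)
  rowSums((f$coefs %*% G) * g$coefs)
}

#' Roughness penalty matrix
#'
#' Entry (j, k) is \eqn{\int D^m b_j(u)\, D^m b_k(u)\, du} for derivative
#' order \code{m}, by polynomial-exact Gauss-Legendre quadrature per knot
#' span. Symmetric positive semi-definite; its null space for \code{m = 2}
#' contains all straight lines.
#'
#' @param basis an \code{fd_basis}.
#' @param derivative_order penalized derivative (must be < spline order).
#' @return \code{dimension x dimension} penalty matrix.
#' @export
penalty_matrix <- function(basis, derivative_order = 2L) {
  stopifnot(inherits(basis, "fd_basis"))
  if (derivative_order >= basis$order)
    stop(sprintf("derivative_order (%d) must be below the spline order (%d)",
                 derivative_order, basis$order))
  if (derivative_order < 0) stop("derivative_order must be non-negative")
  rule <- gl_rule(span_breaks(basis), basis$order + 1L)
  D <- eval_basis(basis, rule$x, deriv = derivative_order)
  P <- t(D) %*% (rule$w * D)
  (P + t(P)) / 2
}
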