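#' Coefficient surface with a historical (triangular band) constraint
#'
#' Represents \eqn{\beta_1(s, t)} as a tensor-product B-spline expansion
#' restricted to the historical band \eqn{t - \mathrm{max\_lag} \le s \le t}:
#' coefficients of tensor pairs whose support does not intersect the band
#' are structurally zero, and evaluation multiplies by the band indicator so
#' the surface is exactly 0 at any (s, t) outside it.
#'
#' @param s_basis,t_basis \code{fd_basis} objects on the same annual domain.
#' @param coefs \code{dim_s x dim_t} coefficient matrix (off-band entries
#'   are zeroed).
#' @param max_lag band width in days (default 60).
#' @return An object of class \code{hist_surface}.
#' @export
hist_surface <- function(s_basis, t_basis, coefs, max_lag = 60) {
  stopifnot(inherits(s_basis, "fd_basis"), inherits(t_basis, "fd_basis"))
  if (!isTRUE(all.equal(s_basis$domain, t_basis$domain)))
    stop("s and t bases must share the annual domain")
  if (max_lag <= 0 || max_lag > diff(s_basis$domain))
    stop("'max_lag' must be positive and at most the domain span")
  coefs <- as.matrix(coefs)
  if (!all(dim(coefs) == c(s_basis$dimension, t_basis$dimension)))
    stop("coefficient matrix dimensions do not match the bases")
  mask <- band_mask(s_basis, t_basis, max_lag)
  coefs[!mask] <- 0
  structure(list(s_basis = s_basis, t_basis = t_basis, coefs = coefs,
                 max_lag = max_lag, mask = mask),
            class = "hist_surface")
}

# TRUE where the support of the (j, k) tensor pair intersects the band
# {(s, t): t - max_lag <= s <= t}.
band_mask <- function(s_basis, t_basis, max_lag) {
  s_lo <- s_basis$knots[seq_len(s_basis$dimension)]
  s_hi <- s_basis$knots[seq_len(s_basis$dimension) + s_basis$order]
  t_lo <- t_basis$knots[seq_len(t_basis$dimension)]
  t_hi <- t_basis$knots[seq_len(t_basis$dimension) + t_basis$order]
  outer(s_lo, t_hi, `<=`) & outer(s_hi, t_lo - max_lag, `>=`)
}

#' Evaluate a historical coefficient surface on a grid
#'
#' @param surface a \code{hist_surface}.
#' @param s_grid,t_grid evaluation grids inside the domain.
#' @return \code{length(s_grid) x length(t_grid)} matrix, exactly 0 outside
#'   the band.
#' @export
eval_surface <- function(surface, s_grid, t_grid) {
  stopifnot(inherits(surface, "hist_surface"))
  Bs <- eval_basis(surface$s_basis, s_grid)
  Bt <- eval_basis(surface$t_basis, t_grid)
  M <- Bs %*% surface$coefs %*% t(Bt)
  off <- outer(s_grid, t_grid, function(s, t) s > t | s < t - surface$max_lag)
  M[off] <- 0
  M
}

#' @export
print.hist_surface <- function(x, ...) {
  cat(sprintf("Historical coefficient surface: %d x %d tensor basis, max lag %g days, %d of %d coefficients in band\n",
              x$s_basis$dimension, x$t_basis$dimension, x$max_lag,
              sum(x$mask), length(x$mask)))
  invisible(x)
}

# Windowed cross-Gram rows: for each t in t_grid, the matrix Q_t with
# entries (a, j) = int_{max(lo, t - max_lag)}^{t} c_a(s) b_j(s) ds, where
# c_a are the temperature-basis functions and b_j the surface s-basis.
# Gauss-Legendre per sub-span clipped to the window, so entries are exact.
window_cross_grams <- function(temp_basis, s_basis, t_grid, max_lag) {
  breaks_all <- sort(unique(c(span_breaks(temp_basis), span_breaks(s_basis))))
  lo <- temp_basis$domain[1]
  n_nodes <- max(temp_basis$order, s_basis$order) + 1L
  lapply(t_grid, function(t) {
    a <- max(lo, t - max_lag); b <- t
    brk <- sort(unique(c(a, breaks_all[breaks_all > a & breaks_all < b], b)))
    rule <- gl_rule(brk, n_nodes)
    Bx <- eval_basis(temp_basis, rule$x)
    Bs <- eval_basis(s_basis, rule$x)
    t(Bx) %*% (rule$w * Bs)
  })
}

#' Historical fully functional linear model for annual mortality curves
#'
#' Fits the function-on-function regression of annual log-mortality curves
#' on same-year temperature,
#' \deqn{\ln(y_i(t)) = s(i) + \beta_0(t)
#'   + \int_{t-60}^{t} x_i(s)\,\beta_1(s,t)\,ds + \epsilon_i(t),}
#' with the historical constraint that only the preceding \code{max_lag}
#' days of temperature may act (for \eqn{t <} \code{max_lag} the integral
#' is truncated at 0 rather than importing the previous year). Temperature
#' curves are centred at their across-year mean curve, so the surface acts
#' on temperature anomalies and \eqn{\beta_0(t)} carries the seasonal
#' mortality profile; \eqn{s(i)} is a natural-spline trend in the year
#' index. The response is discretized on a 365-point grid and the masked
#' tensor-product surface coefficients are estimated by penalized least
#' squares with anisotropic second-derivative penalties in s and t, their
#' weights chosen by generalized cross-validation.
#'
#' @param log_mortality \code{fd_sample} of annual log-mortality curves
#'   (one per year, log scale; see \code{\link{log_rate_curves}}).
#' @param temperature \code{fd_sample} of same-year temperature curves on
#'   the same annual domain.
#' @param max_lag historical band width in days (default 60).
#' @param s_basis,t_basis bases for the surface (defaults: cubic B-splines
#'   of dimension 12 on the annual domain).
#' @param trend_df degrees of freedom of the year-index trend (default 4).
#' @param lambda \code{"gcv"} or fixed \code{c(lambda_s, lambda_t)}.
#' @param lambda_grid dimensionless GCV grid per penalty.
#' @param center centre temperature at the across-year mean curve
#'   (default TRUE; required for identifiability of \eqn{\beta_0}).
#' @return An object of class \code{fflm}.
#' @export
fflm <- function(log_mortality, temperature, max_lag = 60,
                 s_basis = NULL, t_basis = NULL, trend_df = 4L,
                 lambda = "gcv", lambda_grid = 10^seq(-6, 6, length.out = 13),
                 center = TRUE) {
  stopifnot(inherits(log_mortality, "fd_sample"),
            inherits(temperature, "fd_sample"))
  n <- nrow(log_mortality$coefs)
  if (nrow(temperature$coefs) != n)
    stop(sprintf("%d mortality curves but %d temperature curves",
                 n, nrow(temperature$coefs)))
  dom <- log_mortality$basis$domain
  if (!isTRUE(all.equal(dom, temperature$basis$domain)))
    stop("mortality and temperature curves must share the annual domain")
  if (max_lag <= 0 || max_lag > diff(dom))
    stop("'max_lag' must be positive and at most the domain span (days)")
  if (is.null(s_basis)) s_basis <- fd_basis(dom, 8L)
  if (is.null(t_basis)) t_basis <- fd_basis(dom, 8L)

  n_grid <- 365L
  t_grid <- dom[1] + (seq_len(n_grid) - 0.5) * diff(dom) / n_grid
  Y <- eval_fd(log_mortality, t_grid)               # n x 365

  mean_coefs <- colMeans(temperature$coefs)
  Cx <- if (center) sweep(temperature$coefs, 2, mean_coefs) else temperature$coefs

  Q <- window_cross_grams(temperature$basis, s_basis, t_grid, max_lag)
  Ks <- s_basis$dimension; Kt <- t_basis$dimension
  # I_arr[i, j, t] = windowed integral of x_i against s-basis function j
  I_arr <- array(0, c(n, Ks, n_grid))
  for (ti in seq_len(n_grid)) I_arr[, , ti] <- Cx %*% Q[[ti]]

  mask <- band_mask(s_basis, t_basis, max_lag)
  pairs <- which(mask, arr.ind = TRUE)
  nm <- nrow(pairs)
  Bt <- eval_basis(t_basis, t_grid)                 # 365 x Kt

  trend <- year_trend_spec(n, trend_df)
  Tmat <- eval_year_trend(trend, seq_len(n))        # n x df

  p <- ncol(Tmat) + Kt + nm
  X <- matrix(0, n * n_grid, p)
  rowblocks <- split(seq_len(n * n_grid), rep(seq_len(n), each = n_grid))
  Bt_pairs <- Bt[, pairs[, 2], drop = FALSE]        # 365 x nm
  for (i in seq_len(n)) {
    Ii <- t(I_arr[i, , ])                           # 365 x Ks
    X[rowblocks[[i]], ] <- cbind(
      matrix(Tmat[i, ], n_grid, ncol(Tmat), byrow = TRUE),
      Bt,
      Ii[, pairs[, 1], drop = FALSE] * Bt_pairs)
  }
  y <- as.vector(t(Y))

  surf_cols <- (ncol(Tmat) + Kt + 1):p
  Ps <- penalty_matrix(s_basis, 2); Pt <- penalty_matrix(t_basis, 2)
  Gs_id <- diag(Ks); Gt_id <- diag(Kt)
  P_s_blk <- Ps[pairs[, 1], pairs[, 1]] * Gt_id[pairs[, 2], pairs[, 2]]
  P_t_blk <- Gs_id[pairs[, 1], pairs[, 1]] * Pt[pairs[, 2], pairs[, 2]]
  penalties <- list(embed_penalty(P_s_blk, p, surf_cols),
                    embed_penalty(P_t_blk, p, surf_cols))

  # GCV effective sample size: the response grid carries only
  # n_years x dim(mortality basis) free coordinates, not n_years x 365
  n_eff <- n * log_mortality$basis$dimension
  fit <- pls_fit(X, y, penalties = penalties,
                 lambda = if (is.numeric(lambda)) lambda else "gcv",
                 lambda_grid = lambda_grid, n_eff = n_eff)

  Csurf <- matrix(0, Ks, Kt)
  Csurf[pairs] <- fit$coef[surf_cols]
  fitted_grid <- matrix(fit$fitted, n, n_grid, byrow = TRUE)

  structure(list(
    trend_coefs = fit$coef[seq_len(ncol(Tmat))],
    beta0 = fd_sample(t_basis, matrix(fit$coef[ncol(Tmat) + seq_len(Kt)], 1)),
    beta1 = hist_surface(s_basis, t_basis, Csurf, max_lag),
    residual_grid = Y - fitted_grid,
    fitted_grid = fitted_grid,
    response_grid = Y,
    t_grid = t_grid,
    chosen_smoothing = fit$lambda,
    edf = fit$edf,
    n_years = n,
    trend = trend,
    max_lag = max_lag,
    center = center,
    mean_temp_coefs = mean_coefs,
    temp_basis = temperature$basis,
    Q = Q, Bt = Bt, pairs = pairs,
    labels = log_mortality$labels,
    call = match.call()), class = "fflm")
}

year_trend_spec <- function(n, df) {
  df <- max(1L, min(as.integer(df), n - 1L))
  if (df == 1L) return(list(df = 1L, knots = numeric(0), boundary = c(1, n)))
  qs <- seq(0, 1, length.out = df)[-c(1, df)]
  list(df = df, knots = 1 + qs * (n - 1), boundary = c(1, n))
}

eval_year_trend <- function(trend, idx) {
  if (trend$df == 1L)
    return(matrix(idx - trend$boundary[1], ncol = 1))
  N <- splines::ns(idx, knots = trend$knots, Boundary.knots = trend$boundary)
  matrix(N, nrow = length(idx))
}

#' @export
print.fflm <- function(x, ...) {
  cat("Historical fully functional linear model\n")
  cat(sprintf("  %d years, 365-point grid, max lag %g days\n",
              x$n_years, x$max_lag))
  cat(sprintf("  surface %d x %d (in-band coefficients %d), lambda_s %.3g, lambda_t %.3g, edf %.1f\n",
              x$beta1$s_basis$dimension, x$beta1$t_basis$dimension,
              nrow(x$pairs), x$chosen_smoothing[1], x$chosen_smoothing[2],
              x$edf))
  invisible(x)
}

#' @export
summary.fflm <- function(object, ...) {
  r <- object$residual_grid
  out <- list(model = object,
              sigma = sqrt(mean(r^2)),
              r_squared = 1 - sum(r^2) / sum((object$response_grid -
                                              mean(object$response_grid))^2))
  class(out) <- "summary.fflm"
  out
}

#' @export
print.summary.fflm <- function(x, ...) {
  print(x$model)
  cat(sprintf("  residual sd (log scale) %.4f, R-squared %.3f\n",
              x$sigma, x$r_squared))
  invisible(x)
}

#' @export
coef.fflm <- function(object, ...) object$beta1

#' @export
residuals.fflm <- function(object, ...) object$residual_grid

#' @export
fitted.fflm <- function(object, ...) exp(object$fitted_grid)

#' Predict annual mortality curves from an FFLM fit
#'
#' Returns \eqn{\exp(\hat s(i) + \hat\beta_0(t) + \int \hat\beta_1 x)} on
#' the count scale, discretized on the fit's 365-point grid: each row is a
#' year, each column a day, so the matrix \emph{is} the daily predicted
#' mortality series (use \code{\link{discretize_predictions}} to flatten it
#' to one series of the original data length).
#'
#' @param object an \code{fflm} fit.
#' @param temperature \code{fd_sample} of temperature curves for the years
#'   to predict.
#' @param year_indices year index of each curve on the trend scale used in
#'   fitting (training years are \code{1..N}; at most one step beyond is
#'   allowed).
#' @param ... unused.
#' @return \code{n x 365} matrix of predicted daily death counts, with the
#'   log-scale predictions in attribute \code{"log"}.
#' @export
predict.fflm <- function(object, temperature, year_indices, ...) {
  stopifnot(inherits(temperature, "fd_sample"))
  if (!same_basis(temperature$basis, object$temp_basis))
    stop("temperature basis differs from the training basis")
  n_new <- nrow(temperature$coefs)
  if (length(year_indices) != n_new)
    stop("'year_indices' must give one index per temperature curve")
  if (any(year_indices < 0 | year_indices > object$n_years + 1))
    stop("year index beyond the trend range + 1: no long-range trend extrapolation")
  Cx <- temperature$coefs
  if (object$center) Cx <- sweep(Cx, 2, object$mean_temp_coefs)
  n_grid <- length(object$t_grid)
  Tmat <- eval_year_trend(object$trend, year_indices)
  b0 <- drop(object$Bt %*% t(object$beta0$coefs))
  Csurf <- object$beta1$coefs
  logpred <- matrix(0, n_new, n_grid)
  for (i in seq_len(n_new)) {
    hist_int <- vapply(seq_len(n_grid), function(ti) {
      Ij <- drop(Cx[i, ] %*% object$Q[[ti]])
      sum(Ij * (Csurf %*% object$Bt[ti, ]))
    }, numeric(1))
    logpred[i, ] <- sum(Tmat[i, ] * object$trend_coefs) + b0 + hist_int
  }
  out <- exp(logpred)
  attr(out, "log") <- logpred
  attr(out, "t_grid") <- object$t_grid
  out
}

#' Flatten predicted annual curves to one daily series
#'
#' @param pred matrix returned by \code{\link{predict.fflm}} (years in
#'   rows, days in columns).
#' @return numeric vector, years concatenated in row order.
#' @export
discretize_predictions <- function(pred) as.vector(t(pred))

#' Long-format table of the coefficient surface for heatmap rendering
#'
#' @param fit an \code{fflm} fit (or a \code{hist_surface}).
#' @param s_grid,t_grid grids inside the annual domain.
#' @return data frame with columns \code{s}, \code{t}, \code{value};
#'   entries outside the historical band are exactly 0.
#' @export
surface_heatmap_table <- function(fit, s_grid = seq(0, 365, by = 5),
                                  t_grid = seq(0, 365, by = 5)) {
  surf <- if (inherits(fit, "fflm")) fit$beta1 else fit
  stopifnot(inherits(surf, "hist_surface"))
  M <- eval_surface(surf, s_grid, t_grid)
  data.frame(s = rep(s_grid, times = length(t_grid)),
             t = rep(t_grid, each = length(s_grid)),
             value = as.vector(M))
}

#' Plot the FFLM coefficient surface as a heatmap
#'
#' @param x an \code{fflm} fit.
#' @param s_grid,t_grid evaluation grids.
#' @param ... passed to \code{image}.
#' @export
plot.fflm <- function(x, s_grid = seq(0, 365, by = 2),
                      t_grid = seq(0, 365, by = 2), ...) {
  M <- eval_surface(x$beta1, s_grid, t_grid)
  graphics::image(s_grid, t_grid, M, xlab = "exposure day s",
                  ylab = "response day t",
                  col = grDevices::hcl.colors(64, "Blue-Red 2"), ...)
  graphics::abline(a = 0, b = 1, lty = 2)
  graphics::abline(a = -x$max_lag, b = 1, lty = 2)
  invisible(x)
}

#' Smooth daily death counts into annual log-rate curves
#'
#' Smooths each year's daily counts into a positive underlying-rate curve
#' (counts are realizations of a Poisson process whose rate varies slowly
#' over the year), clips the rate at \code{floor} so it is loggable, and
#' returns the log-rate curves on the same basis.
#'
#' @param counts daily death counts.
#' @param dates matching \code{Date}s (Feb 29 must already be excluded).
#' @param basis annual \code{fd_basis} (default: cubic, dimension 16 on
#'   [0, 365]).
#' @param floor minimum rate before logging (default 0.1 deaths/day).
#' @return \code{fd_sample} of log-rate curves, labelled by year.
#' @export
log_rate_curves <- function(counts, dates, basis = NULL, floor = 0.1) {
  if (is.null(basis)) basis <- fd_basis(c(0, 365), 12L)
  rate <- annual_curves(counts, dates, basis)
  grid <- basis$domain[1] + (seq_len(365) - 0.5) * diff(basis$domain) / 365
  vals <- log(pmax(eval_fd(rate, grid), floor))
  fd_smooth(vals, basis, positions = grid, labels = rate$labels)
}

#' Smooth one daily series into per-year annual curves
#'
#' @param values daily measurements (e.g. mean temperature).
#' @param dates matching \code{Date}s; Feb 29 must already be excluded so
#'   every year has 365 values.
#' @param basis annual \code{fd_basis}.
#' @return \code{fd_sample} with one curve per calendar year.
#' @export
annual_curves <- function(values, dates, basis) {
  dates <- as.Date(dates)
  yr <- as.integer(format(dates, "%Y"))
  pos <- doy_no_leap(dates) - 0.5
  split_vals <- split(values, yr)
  split_pos <- split(pos, yr)
  ms <- Map(function(v, p) cbind(p, v), split_vals, split_pos)
  fd_smooth(ms, basis, labels = names(ms))
}

# Day of year with Feb 29 removed from the calendar (1..365 every year).
doy_no_leap <- function(dates) {
  dates <- as.Date(dates)
  yd <- as.POSIXlt(dates)$yday + 1L
  leap <- as.POSIXlt(dates)$year %% 4 == 0 &
    (as.POSIXlt(dates)$year %% 100 != 0 | (as.POSIXlt(dates)$year + 1900) %% 400 == 0)
  feb29 <- format(dates, "%m-%d") == "02-29"
  if (any(feb29)) stop("Feb 29 present: remove leap days first")
  yd - ifelse(leap & yd > 59, 1L, 0L)
}
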