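#' Scalar-response functional linear model for daily mortality
#'
#' Fits the regression of log daily death counts on the previous day's
#' temperature curve,
#' \deqn{\ln(y_i) = s(i) + \beta_0 + \int_0^{24} x_{i-1}(s)\,\beta_1(s)\,ds
#'   + \epsilon_i,}
#' where \eqn{s(i)} is a natural-spline long-term trend with one interior
#' knot every three months of observed data and \eqn{\beta_1(s)} is the
#' functional coefficient of interest, expanded on \code{coef_basis}. Counts
#' enter as \code{ln(max(y, 0.5))} so that rare zero days do not break the
#' log; the functional design columns are the exposure coefficients times
#' the cross-Gram matrix of the exposure and coefficient bases, which
#' implements the integral exactly. \eqn{\beta_1} is estimated by penalized
#' least squares with a second-derivative roughness penalty whose weight is
#' chosen by generalized cross-validation (or fixed via \code{lambda}).
#'
#' @param counts non-negative integer daily death counts.
#' @param dates \code{Date} vector, one per count.
#' @param exposures an \code{\link{fd_sample}} with one curve per count:
#'   the temperature curve of the \emph{previous} day on the exposure
#'   domain (hours 0-24).
#' @param coef_basis \code{fd_basis} for \eqn{\beta_1(s)}; must share the
#'   exposure domain. Default: cubic B-splines, 8 interior knots.
#' @param penalty_order derivative penalized in \eqn{\beta_1} (default 2).
#' @param lambda \code{"gcv"} (default) or a fixed non-negative smoothing
#'   parameter (raw multiplier of the roughness penalty).
#' @param trend_knot_spacing days of observed data between trend knots
#'   (default 91, i.e. one knot every three months).
#' @return An object of class \code{sflm}: see \code{\link{coef.sflm}},
#'   \code{\link{predict.sflm}}, \code{\link{wild_bootstrap_band}}.
#' @seealso \code{\link{fflm}} for the annual-curve companion model.
#' @export
sflm <- function(counts, dates, exposures,
                 coef_basis = NULL, penalty_order = 2L,
                 lambda = "gcv", trend_knot_spacing = 91) {
  if (!inherits(exposures, "fd_sample"))
    stop("'exposures' must be an fd_sample (one temperature curve per day)")
  n <- length(counts)
  if (length(dates) != n)
    stop("'dates' and 'counts' lengths differ")
  if (nrow(exposures$coefs) != n) {
    msg <- sprintf("%d counts but %d exposure curves", n, nrow(exposures$coefs))
    if (!is.null(exposures$labels))
      msg <- paste0(msg, "; unmatched: ",
                    paste(utils::head(setdiff(as.character(dates),
                                              as.character(exposures$labels)), 5),
                          collapse = ", "))
    stop(msg)
  }
  if (any(counts < 0)) stop("death counts must be non-negative")
  if (all(counts == 0)) stop("all counts are zero: log response is degenerate")
  dates <- as.Date(dates)
  if (is.null(coef_basis))
    coef_basis <- fd_basis(exposures$basis$domain, 8L)
  if (!isTRUE(all.equal(coef_basis$domain, exposures$basis$domain)))
    stop("'coef_basis' must live on the exposure domain")

  log_y <- log(pmax(counts, 0.5))
  trend <- trend_spline_spec(dates, trend_knot_spacing)
  Ntrend <- eval_trend(trend, dates)
  J <- gram_matrix(exposures$basis, coef_basis)  # implements the integral
  Z <- exposures$coefs %*% J
  X <- cbind(`(Intercept)` = 1, Ntrend, Z)
  p <- ncol(X)
  beta1_cols <- (p - coef_basis$dimension + 1):p
  Pfull <- embed_penalty(penalty_matrix(coef_basis, penalty_order), p, beta1_cols)

  fit <- pls_fit(X, log_y, penalties = list(Pfull),
                 lambda = if (is.numeric(lambda)) lambda else "gcv")

  trend_cols <- setdiff(seq_len(p), c(1, beta1_cols))
  structure(list(
    beta0 = unname(fit$coef[1]),
    trend_coefs = fit$coef[trend_cols],
    beta1 = fd_sample(coef_basis, matrix(fit$coef[beta1_cols], 1)),
    residuals = unname(log_y - fit$fitted),
    fitted_log = unname(fit$fitted),
    log_responses = log_y,
    counts = counts,
    dates = dates,
    chosen_smoothing = if (length(fit$lambda)) fit$lambda else 0,
    edf = fit$edf,
    coef_basis = coef_basis,
    exposure_basis = exposures$basis,
    cross_gram = J,
    trend = trend,
    X = X, beta1_cols = beta1_cols, penalty = Pfull,
    call = match.call()), class = "sflm")
}

# Natural-spline trend over calendar time; interior knots at every
# `spacing`-th observed day so gapped seasons stay well conditioned.
trend_spline_spec <- function(dates, spacing) {
  x <- as.numeric(sort(unique(dates)))
  idx <- if (length(x) > spacing + 1)
    seq(spacing, length(x) - 1, by = spacing) else integer(0)
  list(knots = x[idx], boundary = range(x), spacing = spacing)
}

eval_trend <- function(trend, dates) {
  x <- as.numeric(as.Date(dates))
  if (length(trend$knots) == 0)
    return(matrix(x - trend$boundary[1], ncol = 1,
                  dimnames = list(NULL, "trend1")))
  N <- splines::ns(x, knots = trend$knots, Boundary.knots = trend$boundary)
  colnames(N) <- paste0("trend", seq_len(ncol(N)))
  N[, , drop = FALSE]
}

#' @export
print.sflm <- function(x, ...) {
  cat("Scalar-response functional linear model\n")
  cat(sprintf("  %d days (%s to %s), trend df %d\n", length(x$counts),
              min(x$dates), max(x$dates), length(x$trend_coefs)))
  cat(sprintf("  beta1 basis dimension %d, smoothing lambda %.4g, total edf %.1f\n",
              x$coef_basis$dimension, x$chosen_smoothing, x$edf))
  invisible(x)
}

#' @export
summary.sflm <- function(object, ...) {
  r <- object$residuals
  out <- list(model = object,
              sigma = sqrt(sum(r^2) / (length(r) - object$edf)),
              r_squared = 1 - sum(r^2) / sum((object$log_responses -
                                              mean(object$log_responses))^2))
  class(out) <- "summary.sflm"
  out
}

#' @export
print.summary.sflm <- function(x, ...) {
  print(x$model)
  cat(sprintf("  residual sd (log scale) %.3f, R-squared %.3f\n",
              x$sigma, x$r_squared))
  invisible(x)
}

#' Extract coefficients from an SFLM fit
#'
#' @param object an \code{sflm} fit.
#' @param which \code{"beta1"} returns the functional coefficient as an
#'   \code{fd_sample}; \code{"all"} the full coefficient vector.
#' @param ... unused.
#' @export
coef.sflm <- function(object, which = c("beta1", "all"), ...) {
  which <- match.arg(which)
  if (which == "beta1") return(object$beta1)
  c(beta0 = object$beta0, object$trend_coefs,
    beta1 = drop(object$beta1$coefs))
}

#' @export
residuals.sflm <- function(object, ...) object$residuals

#' @export
fitted.sflm <- function(object, ...) exp(object$fitted_log)

#' Predict daily death counts from an SFLM fit
#'
#' Returns \eqn{\exp(\hat s(i) + \hat\beta_0 + \int x \hat\beta_1)} on the
#' count scale. The long-term trend is a data-driven spline, so prediction
#' dates may extend at most one knot-spacing past the training calendar
#' range (\code{trend = "limited"}, the default, errors beyond that); with
#' \code{trend = "clamp"} the trend is frozen at its boundary value for
#' out-of-range dates, which is what blocked cross-validation uses for edge
#' years.
#'
#' @param object an \code{sflm} fit.
#' @param exposures \code{fd_sample} of previous-day temperature curves.
#' @param dates prediction dates.
#' @param trend extrapolation rule for the trend spline.
#' @param ... unused.
#' @return numeric vector of predicted counts.
#' @export
predict.sflm <- function(object, exposures, dates,
                         trend = c("limited", "clamp"), ...) {
  trend <- match.arg(trend)
  if (!inherits(exposures, "fd_sample"))
    stop("'exposures' must be an fd_sample")
  if (!same_basis(exposures$basis, object$exposure_basis))
    stop("exposure basis is incompatible with the fitted cross-Gram")
  x <- as.numeric(as.Date(dates))
  b <- object$trend$boundary
  sp <- object$trend$spacing
  if (trend == "limited") {
    if (any(x < b[1] - sp | x > b[2] + sp))
      stop("prediction dates extend more than one knot-spacing past the training range; use trend = \"clamp\" or refit")
  } else {
    x <- pmin(pmax(x, b[1]), b[2])
  }
  Nt <- eval_trend(object$trend, as.Date(x, origin = "1970-01-01"))
  func <- drop(exposures$coefs %*% object$cross_gram %*% t(object$beta1$coefs))
  unname(exp(object$beta0 + drop(Nt %*% object$trend_coefs) + func))
}

#' Wild-bootstrap pointwise confidence band for the functional coefficient
#'
#' Resamples \eqn{y^*_i = \hat y_i + v_i e_i} with independent Rademacher
#' signs \eqn{v_i \in \{-1, +1\}}, refits with the smoothing parameter held
#' at the original fit's value, and returns pointwise 2.5\%/97.5\%
#' percentile bands for \eqn{\beta_1(s)} on \code{grid}. Multiplying the
#' residuals rather than permuting them preserves heteroscedasticity.
#' Because the refit is penalized, replicates are recentred at the point
#' estimate (deviations are taken from the noiseless refit of the fitted
#' values), which removes the first-order re-shrinkage bias: with zero
#' residuals the band collapses onto the point estimate.
#'
#' @param fit an \code{sflm} fit.
#' @param grid evaluation grid on the exposure domain (default 101 points).
#' @param n_bootstrap number of replicates (default 500).
#' @param seed integer seed; same seed gives bit-identical bands.
#' @param level confidence level (default 0.95).
#' @return An object of class \code{sflm_band}: data frame-like list with
#'   \code{grid}, \code{point_estimate}, \code{lower}, \code{upper},
#'   \code{n_replicates}.
#' @export
wild_bootstrap_band <- function(fit, grid = NULL, n_bootstrap = 500L,
                                seed = NULL, level = 0.95) {
  stopifnot(inherits(fit, "sflm"))
  if (n_bootstrap < 1) stop("'n_bootstrap' must be at least 1")
  if (n_bootstrap < 40)
    warning("fewer than 40 replicates: percentile bands will be unstable")
  if (is.null(grid))
    grid <- seq(fit$coef_basis$domain[1], fit$coef_basis$domain[2],
                length.out = 101)
  if (!is.null(seed)) set.seed(seed)
  n <- length(fit$residuals)
  X <- fit$X
  M <- crossprod(X) + fit$chosen_smoothing * fit$penalty
  A <- solve(M, t(X))                       # refit operator at the same lambda
  h <- rowSums(X * t(A))                    # leverages of the penalized smoother
  e <- fit$residuals / sqrt(pmax(1 - h, 0.01))  # HC2: undo residual deflation
  V <- matrix(sample(c(-1, 1), n * n_bootstrap, replace = TRUE), n)
  Ystar <- fit$fitted_log + e * V
  Theta <- A %*% Ystar                      # p x B coefficient replicates
  theta0 <- A %*% fit$fitted_log            # noiseless refit (re-shrunk)
  E <- eval_basis(fit$coef_basis, grid)
  Bcurves <- E %*% (Theta[fit$beta1_cols, , drop = FALSE] -
                    drop(theta0)[fit$beta1_cols])  # deviations, grid x B
  est <- drop(eval_fd(fit$beta1, grid))
  alpha <- (1 - level) / 2
  qs <- apply(Bcurves, 1, stats::quantile, probs = c(alpha, 1 - alpha),
              names = FALSE)
  structure(list(grid = grid,
                 point_estimate = est,
                 lower = est + qs[1, ], upper = est + qs[2, ],
                 n_replicates = as.integer(n_bootstrap), level = level),
            class = "sflm_band")
}

#' @export
print.sflm_band <- function(x, ...) {
  cat(sprintf("Wild-bootstrap %g%% pointwise band, %d replicates, %d grid points\n",
              100 * x$level, x$n_replicates, length(x$grid)))
  invisible(x)
}

#' Plot the functional coefficient of an SFLM fit
#'
#' @param x an \code{sflm} fit.
#' @param band optional \code{sflm_band} to overlay as dashed lines.
#' @param ... passed to \code{plot}.
#' @export
plot.sflm <- function(x, band = NULL, ...) {
  grid <- if (is.null(band))
    seq(x$coef_basis$domain[1], x$coef_basis$domain[2], length.out = 101)
  else band$grid
  est <- drop(eval_fd(x$beta1, grid))
  ylim <- if (is.null(band)) range(est) else range(est, band$lower, band$upper)
  plot(grid, est, type = "l", xlab = "hour of previous day",
       ylab = expression(beta[1](s)), ylim = ylim, ...)
  if (!is.null(band)) {
    graphics::lines(band$grid, band$lower, lty = 2)
    graphics::lines(band$grid, band$upper, lty = 2)
  }
  graphics::abline(h = 0, col = "grey")
  invisible(x)
}
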