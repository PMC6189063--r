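#' Daily temperature summaries from hourly readings
#'
#' Collapses hourly temperature to the classical scalar exposure variables:
#' minimum, mean, maximum and diurnal range (max - min). A day with fewer
#' than \code{min_hours} of its 24 readings present is flagged missing
#' (all-NA summaries) rather than silently summarized.
#'
#' @param hourly data frame with columns \code{date}, \code{hour},
#'   \code{temp}.
#' @param min_hours minimum readings for a valid day (default 18).
#' @return data frame with columns \code{date}, \code{t_min},
#'   \code{t_mean}, \code{t_max}, \code{diurnal_range}, \code{missing}.
#' @export
summarize_day <- function(hourly, min_hours = 18L) {
  stopifnot(all(c("date", "hour", "temp") %in% names(hourly)))
  days <- split(hourly$temp, hourly$date)
  out <- data.frame(date = as.Date(names(days)))
  stats_ <- t(vapply(days, function(v) {
    v <- v[is.finite(v)]
    if (length(v) < min_hours) return(c(NA_real_, NA_real_, NA_real_, NA_real_))
    c(min(v), mean(v), max(v), max(v) - min(v))
  }, numeric(4)))
  out$t_min <- stats_[, 1]; out$t_mean <- stats_[, 2]
  out$t_max <- stats_[, 3]; out$diurnal_range <- stats_[, 4]
  out$missing <- is.na(out$t_mean)
  rownames(out) <- NULL
  out
}

#' Classical lag-1 temperature GAM baseline
#'
#' Gaussian regression of \code{ln(max(count, 0.5))} on a natural-spline
#' long-term trend (one knot per three months of observed data, as in
#' \code{\link{sflm}}) plus a penalized cubic regression spline in one
#' scalar summary of the \emph{previous} day's temperature, fitted with
#' \pkg{mgcv} (10 basis functions, GCV-chosen smoothing).
#'
#' @param counts daily death counts.
#' @param dates matching \code{Date}s.
#' @param summaries output of \code{\link{summarize_day}} covering the
#'   \emph{previous} day of each count (i.e. already lag-aligned: row i is
#'   the summary of day \code{dates[i] - 1}).
#' @param which which summary drives the smooth: \code{"min"},
#'   \code{"mean"}, \code{"max"} or \code{"dr"} (diurnal range).
#' @param trend_knot_spacing as in \code{\link{sflm}}.
#' @return An object of class \code{lag_gam} wrapping the \pkg{mgcv} fit.
#' @export
lag_gam <- function(counts, dates, summaries,
                    which = c("mean", "min", "max", "dr"),
                    trend_knot_spacing = 91) {
  which <- match.arg(which)
  col <- c(mean = "t_mean", min = "t_min", max = "t_max",
           dr = "diurnal_range")[which]
  n <- length(counts)
  if (length(dates) != n || nrow(summaries) != n)
    stop("counts, dates and summaries must be aligned (one row per day)")
  x <- summaries[[col]]
  if (mean(is.na(x)) > 0.10)
    stop(sprintf("summary '%s' missing for more than 10%% of days", which))
  dates <- as.Date(dates)
  trend <- trend_spline_spec(dates, trend_knot_spacing)
  dat <- data.frame(log_y = log(pmax(counts, 0.5)), x = x)
  dat$Ntrend <- eval_trend(trend, dates)
  gfit <- mgcv::gam(log_y ~ Ntrend + s(x, bs = "cr", k = 10), data = dat,
                    method = "GCV.Cp", na.action = stats::na.exclude)
  structure(list(kind = paste0("gam_", which), which = which, fit = gfit,
                 trend = trend, dates = dates, counts = counts,
                 call = match.call()), class = "lag_gam")
}

#' @export
print.lag_gam <- function(x, ...) {
  cat(sprintf("Lag-1 temperature GAM baseline (%s), %d days, smooth edf %.2f\n",
              x$kind, length(x$counts), sum(x$fit$edf[x$fit$smooth[[1]]$first.para:
                                                      x$fit$smooth[[1]]$last.para])))
  invisible(x)
}

#' @export
residuals.lag_gam <- function(object, ...) stats::residuals(object$fit)

#' Predict counts from a lag-1 GAM baseline
#'
#' @param object a \code{lag_gam} fit.
#' @param dates prediction dates.
#' @param summaries previous-day summaries aligned with \code{dates}.
#' @param ... unused.
#' @return predicted counts (count scale). Temperatures outside the
#'   training range are clamped to it (regression splines do not
#'   extrapolate stably).
#' @export
predict.lag_gam <- function(object, dates, summaries, ...) {
  col <- c(mean = "t_mean", min = "t_min", max = "t_max",
           dr = "diurnal_range")[object$which]
  x <- summaries[[col]]
  rng <- range(object$fit$model$x, na.rm = TRUE)
  b <- object$trend$boundary
  xd <- pmin(pmax(as.numeric(as.Date(dates)), b[1]), b[2])  # clamp trend
  nd <- list(x = pmin(pmax(x, rng[1]), rng[2]),
             Ntrend = eval_trend(object$trend, as.Date(xd, origin = "1970-01-01")))
  exp(as.numeric(mgcv::predict.gam(object$fit, newdata = nd)))
}

#' Distributed-lag cross-basis over temperature and lag
#'
#' Builds the DLNM design: for each day i the row is
#' \eqn{\sum_{l=0}^{L} b_{temp}(x_{i-l}) \otimes b_{lag}(l)}, with cubic
#' B-spline marginal bases. Interior temperature knots sit at the 10th,
#' 75th and 90th percentiles of the observed series; interior lag knots at
#' values equally spaced on the \code{log(lag + 1)} scale (so lag 0 is
#' included). Days without a complete lag history are flagged.
#'
#' @param daily_temps numeric vector of daily temperatures.
#' @param max_lag maximum lag in days (default 60).
#' @param temp_percentiles interior temperature knot percentiles.
#' @param n_lag_knots number of interior lag knots (default 5).
#' @return An object of class \code{crossbasis}: list with the
#'   \code{design} matrix (\code{n x dim_temp*dim_lag}), the marginal
#'   bases, and \code{complete} (logical: full history available).
#' @export
build_crossbasis <- function(daily_temps, max_lag = 60L,
                             temp_percentiles = c(10, 75, 90),
                             n_lag_knots = 5L) {
  n <- length(daily_temps)
  if (max_lag >= n)
    stop("'max_lag' must be smaller than the series length")
  rng <- range(daily_temps)
  if (diff(rng) <= 0)
    stop("temperature series is constant: no cross-basis is identifiable")
  tk <- stats::quantile(daily_temps, temp_percentiles / 100)
  tk <- unique(tk[tk > rng[1] & tk < rng[2]])  # degenerate percentiles dropped
  tb <- fd_basis_knots(rng, tk, order = 4L)
  lag_interior <- exp(seq(0, log(max_lag + 1),
                          length.out = n_lag_knots + 2L)[-c(1, n_lag_knots + 2L)]) - 1
  lb <- fd_basis_knots(c(0, max_lag), lag_interior, order = 4L)

  Tm <- eval_basis(tb, daily_temps)            # n x dim_temp
  Lm <- eval_basis(lb, 0:max_lag)              # (L+1) x dim_lag
  dt <- tb$dimension; dl <- lb$dimension
  D <- matrix(0, n, dt * dl)
  for (l in 0:max_lag) {
    rows <- (l + 1):n
    shifted <- Tm[rows - l, , drop = FALSE]
    # column block order: (temp j, lag k) -> column (k - 1) * dt + j
    for (k in seq_len(dl)) {
      cols <- (k - 1) * dt + seq_len(dt)
      D[rows, cols] <- D[rows, cols] + shifted * Lm[l + 1, k]
    }
  }
  complete <- c(rep(FALSE, max_lag), rep(TRUE, n - max_lag))
  structure(list(design = D, temp_basis = tb, lag_basis = lb,
                 max_lag = as.integer(max_lag), complete = complete,
                 temp_range = rng),
            class = "crossbasis")
}

#' @export
print.crossbasis <- function(x, ...) {
  cat(sprintf("DLNM cross-basis: %d days, temp dim %d x lag dim %d = %d columns, max lag %d\n",
              nrow(x$design), x$temp_basis$dimension, x$lag_basis$dimension,
              ncol(x$design), x$max_lag))
  invisible(x)
}

#' Distributed lag non-linear model baseline
#'
#' Gaussian regression of \code{ln(max(count, 0.5))} on a slow long-term
#' trend spline (one knot per year of observed data), day-of-year
#' harmonics shared across years for the seasonal mortality cycle, and
#' the ridge-penalized cross-basis columns (smoothing weight by GCV).
#' Season must be carried by terms that transfer across years — a
#' flexible calendar-time spline would fit each year's cycle in-sample
#' but cannot predict a held-out year. With \code{doy_interaction = TRUE}
#' the cross-basis columns are additionally multiplied by one
#' \code{sin/cos} harmonic of the day of year, letting the
#' lag-temperature response vary over the season. Days without a complete
#' lag history are excluded from the fit.
#'
#' @param counts daily death counts aligned with the cross-basis rows.
#' @param dates matching \code{Date}s.
#' @param crossbasis a \code{\link{build_crossbasis}} object.
#' @param doy_interaction add the day-of-year interaction harmonic.
#' @param trend_knot_spacing days of observed data between trend knots
#'   (default 365: the trend carries only multi-year drift).
#' @param season_harmonics number of annual \code{sin/cos} harmonic pairs
#'   for the seasonal cycle (default 2).
#' @param lambda \code{"gcv"} or a fixed ridge weight.
#' @return An object of class \code{dlnm}.
#' @export
dlnm <- function(counts, dates, crossbasis, doy_interaction = FALSE,
                 trend_knot_spacing = 365, season_harmonics = 2L,
                 lambda = "gcv") {
  stopifnot(inherits(crossbasis, "crossbasis"))
  n <- length(counts)
  if (nrow(crossbasis$design) != n || length(dates) != n)
    stop("counts, dates and cross-basis rows must be aligned")
  dates <- as.Date(dates)
  keep <- crossbasis$complete
  log_y <- log(pmax(counts, 0.5))
  trend <- trend_spline_spec(dates[keep], trend_knot_spacing)
  Nt <- eval_trend(trend, dates[keep])
  CB <- crossbasis$design[keep, , drop = FALSE]
  doy <- doy_no_leap_safe(dates[keep])
  H <- season_harmonic_cols(doy, season_harmonics)
  blocks <- list(CB)
  if (doy_interaction) {
    blocks <- c(blocks, list(CB * sin(2 * pi * doy / 365),
                             CB * cos(2 * pi * doy / 365)))
  }
  X <- do.call(cbind, c(list(`(Intercept)` = 1, Nt, H), blocks))
  p <- ncol(X)
  nfixed <- 1 + ncol(Nt) + ncol(H)
  pen_cols <- (nfixed + 1):p
  Pfull <- embed_penalty(diag(length(pen_cols)), p, pen_cols)
  fit <- tryCatch(
    pls_fit(X, log_y[keep], penalties = list(Pfull),
            lambda = if (is.numeric(lambda)) lambda else "gcv"),
    error = function(e) {
      kap <- tryCatch(kappa(crossprod(X)), error = function(e2) Inf)
      stop(sprintf("singular penalized system (condition number %.3g): %s",
                   kap, conditionMessage(e)))
    })
  structure(list(kind = if (doy_interaction) "dlnm_doy" else "dlnm",
                 coefficients = fit$coef, trend = trend,
                 season_harmonics = season_harmonics,
                 crossbasis = crossbasis[c("temp_basis", "lag_basis",
                                           "max_lag", "temp_range")],
                 doy_interaction = doy_interaction,
                 chosen_smoothing = if (length(fit$lambda)) fit$lambda else 0,
                 edf = fit$edf, nfixed = nfixed,
                 residuals = log_y[keep] - fit$fitted,
                 fitted_log = fit$fitted, keep = keep, dates = dates,
                 call = match.call()), class = "dlnm")
}

season_harmonic_cols <- function(doy, n_harmonics) {
  if (n_harmonics < 1) return(matrix(0, length(doy), 0))
  do.call(cbind, lapply(seq_len(n_harmonics), function(k)
    cbind(sin(2 * pi * k * doy / 365), cos(2 * pi * k * doy / 365))))
}

#' @export
print.dlnm <- function(x, ...) {
  cat(sprintf("DLNM baseline (%s): %d days fitted, ridge lambda %.4g, edf %.1f\n",
              x$kind, sum(x$keep), x$chosen_smoothing, x$edf))
  invisible(x)
}

#' @export
residuals.dlnm <- function(object, ...) object$residuals

#' Predict counts from a DLNM baseline
#'
#' @param object a \code{dlnm} fit.
#' @param dates prediction dates.
#' @param daily_temps full temperature history ending at the last
#'   prediction date (needed to rebuild lagged rows); temperatures are
#'   clamped to the training range before basis evaluation.
#' @param trend extrapolation rule for the trend spline, as in
#'   \code{\link{predict.sflm}}.
#' @param ... unused.
#' @return predicted counts for the last \code{length(dates)} days of the
#'   supplied history.
#' @export
predict.dlnm <- function(object, dates, daily_temps,
                         trend = c("limited", "clamp"), ...) {
  trend <- match.arg(trend)
  dates <- as.Date(dates)
  n_out <- length(dates)
  temps <- pmin(pmax(daily_temps, object$crossbasis$temp_range[1]),
                object$crossbasis$temp_range[2])
  L <- object$crossbasis$max_lag
  n_short <- max(0L, n_out + L - length(temps))  # days without full history -> NA
  Tm <- eval_basis(object$crossbasis$temp_basis, temps)
  Lm <- eval_basis(object$crossbasis$lag_basis, 0:L)
  dt <- ncol(Tm); dl <- ncol(Lm)
  offset <- length(temps) - n_out
  D <- matrix(0, n_out, dt * dl)
  for (l in 0:L) {
    rows <- which(offset + seq_len(n_out) - l >= 1)
    shifted <- Tm[offset + rows - l, , drop = FALSE]
    for (k in seq_len(dl)) {
      cols <- (k - 1) * dt + seq_len(dt)
      D[rows, cols] <- D[rows, cols] + shifted * Lm[l + 1, k]
    }
  }
  x <- as.numeric(dates)
  b <- object$trend$boundary; sp <- object$trend$spacing
  if (trend == "limited") {
    if (any(x < b[1] - sp | x > b[2] + sp))
      stop("prediction dates extend more than one knot-spacing past the training range; use trend = \"clamp\"")
  } else x <- pmin(pmax(x, b[1]), b[2])
  Nt <- eval_trend(object$trend, as.Date(x, origin = "1970-01-01"))
  doy <- doy_no_leap_safe(dates)
  H <- season_harmonic_cols(doy, object$season_harmonics)
  blocks <- list(D)
  if (object$doy_interaction) {
    blocks <- c(blocks, list(D * sin(2 * pi * doy / 365),
                             D * cos(2 * pi * doy / 365)))
  }
  X <- do.call(cbind, c(list(1, Nt, H), blocks))
  out <- exp(drop(X %*% object$coefficients))
  if (n_short > 0) out[seq_len(n_short)] <- NA_real_
  out
}
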