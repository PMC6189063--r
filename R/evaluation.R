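#' Root mean square error
#'
#' @param predicted,observed numeric vectors of equal length, no missing
#'   values.
#' @return \eqn{\sqrt{\mathrm{mean}((p - o)^2)}}.
#' @export
rmse <- function(predicted, observed) {
  if (length(predicted) != length(observed))
    stop("'predicted' and 'observed' lengths differ")
  if (anyNA(predicted) || anyNA(observed))
    stop("missing values in RMSE inputs")
  sqrt(mean((predicted - observed)^2))
}

#' Leave-one-year-out fold plan
#'
#' @param dates observation dates; each calendar year is one fold.
#' @return list with \code{fold_labels} (per observation) and
#'   \code{n_folds}.
#' @export
fold_plan_by_year <- function(dates) {
  yr <- format(as.Date(dates), "%Y")
  list(fold_labels = yr, n_folds = length(unique(yr)))
}

#' Blocked (leave-one-year-out) cross-validated RMSE
#'
#' For each calendar-year fold, the chosen model is refitted on the
#' remaining years and the held-out year is predicted on the count scale
#' (functional predictions are discretized to daily values first). All
#' held-out squared errors are pooled before the square root, giving one
#' global RMSE; per-fold RMSEs are returned for diagnostics. Folds are
#' contiguous year blocks so serial dependence does not leak between
#' training and test sets.
#'
#' @param model one of \code{"sflm"}, \code{"gam_min"}, \code{"gam_mean"},
#'   \code{"gam_max"}, \code{"gam_dr"} (daily application:
#'   \code{data = synth_sflm_dataset()}-shaped list with \code{counts},
#'   \code{exposures}, \code{hourly}), or \code{"fflm"}, \code{"dlnm"},
#'   \code{"dlnm_doy"} (annual application: \code{synth_fflm_dataset()}-
#'   shaped list with \code{daily}, plus \code{temperature} and
#'   \code{log_mortality} bases for the FFLM).
#' @param data the data bundle described above.
#' @param ... passed to the underlying fitting function.
#' @return list with \code{rmse} (pooled), \code{per_fold} (data frame
#'   \code{fold}, \code{n}, \code{rmse}), \code{predictions} (in data
#'   order, NA where unscored).
#' @export
blocked_cv_rmse <- function(model = c("sflm", "gam_min", "gam_mean",
                                      "gam_max", "gam_dr",
                                      "fflm", "dlnm", "dlnm_doy"),
                            data, ...) {
  model <- match.arg(model)
  if (model %in% c("sflm", "gam_min", "gam_mean", "gam_max", "gam_dr"))
    cv_daily(model, data, ...)
  else
    cv_annual(model, data, ...)
}

cv_daily <- function(model, data, ...) {
  counts <- data$counts$count
  dates <- as.Date(data$counts$date)
  plan <- fold_plan_by_year(dates)
  folds <- sort(unique(plan$fold_labels))
  summaries <- if (startsWith(model, "gam")) {
    s <- summarize_day(data$hourly)
    s[match(dates - 1, s$date), , drop = FALSE]  # previous-day summary per count
  } else NULL
  preds <- rep(NA_real_, length(counts))
  per <- data.frame(fold = folds, n = NA_integer_, rmse = NA_real_)
  failed <- character(0)
  for (f in folds) {
    test <- plan$fold_labels == f
    train <- !test
    stopifnot(!any(test & train), sum(test) + sum(train) == length(counts))
    res <- tryCatch({
      if (model == "sflm") {
        ex_tr <- fd_sample(data$exposures$basis,
                           data$exposures$coefs[train, , drop = FALSE])
        ex_te <- fd_sample(data$exposures$basis,
                           data$exposures$coefs[test, , drop = FALSE])
        fit <- sflm(counts[train], dates[train], ex_tr, ...)
        predict(fit, ex_te, dates[test], trend = "clamp")
      } else {
        which <- sub("gam_", "", model)
        fit <- lag_gam(counts[train], dates[train],
                       summaries[train, , drop = FALSE], which = which, ...)
        predict(fit, dates[test], summaries[test, , drop = FALSE])
      }
    }, error = function(e) e)
    if (inherits(res, "error")) { failed <- c(failed, f); next }
    preds[test] <- res
    per$n[per$fold == f] <- sum(test)
    per$rmse[per$fold == f] <- rmse(res, counts[test])
  }
  pooled <- if (length(failed)) NA_real_ else {
    sc <- !is.na(preds)
    rmse(preds[sc], counts[sc])
  }
  list(rmse = pooled, per_fold = per, predictions = preds,
       failed_folds = failed, model = model)
}

cv_annual <- function(model, data, ...) {
  daily <- data$daily
  dates <- as.Date(daily$date)
  plan <- fold_plan_by_year(dates)
  folds <- sort(unique(plan$fold_labels))
  preds <- rep(NA_real_, nrow(daily))
  per <- data.frame(fold = folds, n = NA_integer_, rmse = NA_real_)
  failed <- character(0)

  if (model == "fflm") {
    temp_all <- data$temperature
    mort_all <- data$log_mortality
    yrs <- as.character(temp_all$labels)
    for (f in folds) {
      test_day <- plan$fold_labels == f
      tr <- yrs != f
      res <- tryCatch({
        fit <- fflm(fd_sample(mort_all$basis, mort_all$coefs[tr, , drop = FALSE],
                              mort_all$labels[tr]),
                    fd_sample(temp_all$basis, temp_all$coefs[tr, , drop = FALSE],
                              temp_all$labels[tr]), ...)
        # trend index of the held-out year on the training index scale
        pos <- match(f, yrs)
        idx <- if (pos == 1) 0 else if (pos == length(yrs)) sum(tr) + 1
               else pos - 0.5
        pm <- predict(fit,
                      fd_sample(temp_all$basis,
                                temp_all$coefs[!tr, , drop = FALSE]),
                      year_indices = idx)
        discretize_predictions(pm)
      }, error = function(e) e)
      if (inherits(res, "error")) { failed <- c(failed, f); next }
      preds[test_day] <- res
      per$n[per$fold == f] <- sum(test_day)
      per$rmse[per$fold == f] <- rmse(res, daily$count[test_day])
    }
  } else {
    cb <- build_crossbasis(daily$temp, ...)
    L <- cb$max_lag
    for (f in folds) {
      test <- plan$fold_labels == f
      train <- !test
      res <- tryCatch({
        cb_tr <- cb
        cb_tr$design <- cb$design[train, , drop = FALSE]
        cb_tr$complete <- cb$complete[train]
        fit <- dlnm(daily$count[train], dates[train], cb_tr,
                    doy_interaction = (model == "dlnm_doy"))
        first <- which(test)[1]
        hist_idx <- max(1, first - L):max(which(test))
        predict(fit, dates[test], daily$temp[hist_idx], trend = "clamp")
      }, error = function(e) e)
      if (inherits(res, "error")) { failed <- c(failed, f); next }
      preds[test] <- res
      ok <- !is.na(res)  # days without full lag history are not scored
      per$n[per$fold == f] <- sum(ok)
      per$rmse[per$fold == f] <- rmse(res[ok], daily$count[test][ok])
    }
  }
  pooled <- if (length(failed)) NA_real_ else {
    sc <- !is.na(preds)
    rmse(preds[sc], daily$count[sc])
  }
  list(rmse = pooled, per_fold = per, predictions = preds,
       failed_folds = failed, model = model)
}

#' Blocked-CV RMSE comparison table across models
#'
#' Runs \code{\link{blocked_cv_rmse}} for several models on the same data
#' bundle and returns one row per model, mirroring the usual
#' model-by-RMSE results table.
#'
#' @param models character vector of model names.
#' @param data data bundle (see \code{\link{blocked_cv_rmse}}).
#' @param ... passed through.
#' @return data frame with columns \code{model}, \code{rmse}.
#' @export
cv_comparison <- function(models, data, ...) {
  res <- lapply(models, function(m) blocked_cv_rmse(m, data, ...))
  data.frame(model = models,
             rmse = vapply(res, function(r) r$rmse, numeric(1)))
}
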