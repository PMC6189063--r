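#' Synthetic weather-mortality scenario
#'
#' Seeded description of a data-generating process emulating the
#' statistical structure of an urban temperature-mortality study: smooth
#' seasonal (and, for hourly data, diurnal) temperature cycles with AR(1)
#' noise, and daily death counts drawn from a Poisson distribution whose
#' log-rate contains a slow trend plus a functional exposure term with a
#' known coefficient. Defaults are calibrated to the descriptive scale of
#' a large northern metropolitan area: mean daily cardiovascular mortality
#' around 17 deaths, annual temperature cycle of amplitude 15 degC around a
#' 6.5 degC mean, diurnal amplitude 4 degC.
#'
#' @param mode \code{"sflm"} (hourly summer temperature, daily counts) or
#'   \code{"fflm"} (daily temperature and counts over whole years).
#' @param seed integer seed; everything downstream is reproducible from it.
#' @param years calendar years covered (defaults: 2007-2011 summers for
#'   \code{sflm}, 1981-2011 for \code{fflm}).
#' @param baseline_log_rate log of the baseline daily death rate
#'   (default \code{log(17)}).
#' @param trend_amplitude half-range of the slow linear trend in the
#'   log-rate over the whole period.
#' @param true_beta1 the true functional coefficient: an
#'   \code{\link{fd_sample}} on [0, 24] (\code{sflm} mode; default: the
#'   L2 projection of \eqn{\sin(2\pi s/24)/24} onto a dimension-12 cubic
#'   basis) or a \code{\link{hist_surface}} (\code{fflm} mode; default: a
#'   smooth, mostly negative surface on the 60-day band whose strength
#'   varies over the season).
#' @param temp_mean annual mean temperature (degC).
#' @param temp_seasonal_amplitude,temp_seasonal_phase amplitude (degC) and
#'   day-of-year of the seasonal temperature peak.
#' @param temp_diurnal_amplitude,temp_diurnal_phase amplitude (degC) and
#'   peak hour of the diurnal cycle (hourly mode only).
#' @param noise_ar,noise_sd AR(1) coefficient (per time step: hour in
#'   \code{sflm} mode, day in \code{fflm} mode) and innovation SD (degC).
#' @param mort_seasonal_amplitude winter excess of the log mortality rate
#'   (\code{fflm} mode; peak in late January).
#' @param overdispersion \code{NULL} for pure Poisson counts, or a gamma
#'   shape parameter for gamma-mixed (negative-binomial-like) counts.
#' @return An object of class \code{mort_scenario}.
#' @export
mort_scenario <- function(mode = c("sflm", "fflm"), seed = 1L,
                          years = NULL,
                          baseline_log_rate = log(17),
                          trend_amplitude = if (mode == "sflm") 0.05 else 0.1,
                          true_beta1 = NULL,
                          temp_mean = 6.5,
                          temp_seasonal_amplitude = 15,
                          temp_seasonal_phase = 205,
                          temp_diurnal_amplitude = 4,
                          temp_diurnal_phase = 15,
                          noise_ar = if (mode == "sflm") 0.97 else 0.75,
                          noise_sd = if (mode == "sflm") 0.6 else 2.6,
                          mort_seasonal_amplitude = 0.15,
                          overdispersion = NULL) {
  mode <- match.arg(mode)
  if (is.null(years)) years <- if (mode == "sflm") 2007:2011 else 1981:2011
  if (length(years) < 1) stop("at least one year is required")
  if (abs(noise_ar) >= 1) stop("AR(1) coefficient must lie in (-1, 1)")
  if (!is.finite(baseline_log_rate)) stop("baseline rate must be finite")
  if (is.null(true_beta1)) {
    true_beta1 <- if (mode == "sflm") default_beta1_curve(amplitude = 0.25)
                  else default_beta1_surface()
  }
  if (mode == "sflm" && !inherits(true_beta1, "fd_sample"))
    stop("'true_beta1' must be an fd_sample in sflm mode")
  if (mode == "fflm" && !inherits(true_beta1, "hist_surface"))
    stop("'true_beta1' must be a hist_surface in fflm mode")
  structure(list(mode = mode, seed = as.integer(seed), years = years,
                 baseline_log_rate = baseline_log_rate,
                 trend_amplitude = trend_amplitude,
                 true_beta1 = true_beta1,
                 temp_mean = temp_mean,
                 temp_seasonal_amplitude = temp_seasonal_amplitude,
                 temp_seasonal_phase = temp_seasonal_phase,
                 temp_diurnal_amplitude = temp_diurnal_amplitude,
                 temp_diurnal_phase = temp_diurnal_phase,
                 noise_ar = noise_ar, noise_sd = noise_sd,
                 mort_seasonal_amplitude = mort_seasonal_amplitude,
                 overdispersion = overdispersion),
            class = "mort_scenario")
}

#' @export
print.mort_scenario <- function(x, ...) {
  cat(sprintf("Synthetic weather-mortality scenario (%s mode), seed %d, years %d-%d\n",
              x$mode, x$seed, min(x$years), max(x$years)))
  invisible(x)
}

#' Reference true functional coefficient for the daily application
#'
#' The L2 projection of \eqn{a \sin(2\pi s/24)/24} onto a dimension-12
#' cubic basis on [0, 24]. At \code{amplitude = 1} this is the canonical
#' parameter-recovery coefficient; the scenario default uses
#' \code{amplitude = 0.25}, which together with the default temperature
#' variability gives daily counts of mean 17 and SD about 5.
#'
#' @param amplitude multiplier \eqn{a}.
#' @return single-curve \code{\link{fd_sample}}.
#' @export
default_beta1_curve <- function(amplitude = 1) {
  basis <- fd_basis(c(0, 24), 8L)
  grid <- seq(0, 24, length.out = 481)
  cf <- qr.coef(qr(eval_basis(basis, grid)),
                amplitude * sin(2 * pi * grid / 24) / 24)
  fd_sample(basis, matrix(cf, 1))
}

#' Reference true coefficient surface for the annual application
#'
#' A smooth, mostly negative surface on the 60-day historical band whose
#' strength varies over the season (strong in the transition seasons,
#' weak mid-winter) and decays with lag; coefficients are set at the
#' Greville centres of a 12 x 12 cubic tensor basis. The default
#' amplitude makes the historical term's SD about 0.1 on the log-rate
#' scale, comparable to the seasonal winter excess.
#'
#' @param amplitude overall scale of the surface.
#' @param max_lag band width in days.
#' @return a \code{\link{hist_surface}}.
#' @export
default_beta1_surface <- function(amplitude = 0.0045, max_lag = 60) {
  s_basis <- fd_basis(c(0, 365), 8L)
  t_basis <- fd_basis(c(0, 365), 8L)
  tau_s <- greville(s_basis); tau_t <- greville(t_basis)
  C <- outer(seq_along(tau_s), seq_along(tau_t), function(j, k) {
    lag <- tau_t[k] - tau_s[j]
    -amplitude * (0.5 + 0.5 * cos(2 * pi * (tau_t[k] - 300) / 365)) *
      exp(-pmax(lag, 0) / 30)
  })
  hist_surface(s_basis, t_basis, C, max_lag)
}

greville <- function(basis) {
  vapply(seq_len(basis$dimension), function(j)
    mean(basis$knots[(j + 1):(j + basis$order - 1)]), numeric(1))
}

#' Simulate a temperature series from a scenario
#'
#' The series is a seasonal sinusoid plus (hourly mode) a diurnal sinusoid
#' plus AR(1) noise. In \code{sflm} mode, hourly values are generated for
#' June-August of each scenario year plus the preceding day (May 31), so
#' that every summer day has a previous-day exposure curve; the AR state
#' restarts from its stationary law each summer. In \code{fflm} mode one
#' continuous daily series covers all years, with Feb 29 excluded.
#'
#' @param scenario a \code{\link{mort_scenario}}.
#' @return data frame with columns \code{date}, (\code{hour},) \code{temp};
#'   the deterministic (noise-free) component is in column \code{temp_mean}.
#' @export
simulate_temperature <- function(scenario) {
  stopifnot(inherits(scenario, "mort_scenario"))
  set.seed(scenario$seed)
  sc <- scenario
  stat_sd <- sc$noise_sd / sqrt(1 - sc$noise_ar^2)
  if (sc$mode == "sflm") {
    blocks <- lapply(sc$years, function(yr) {
      dates <- seq(as.Date(sprintf("%d-05-31", yr)),
                   as.Date(sprintf("%d-08-31", yr)), by = "day")
      data.frame(date = rep(dates, each = 24L), hour = rep(0:23, length(dates)))
    })
    out <- do.call(rbind, blocks)
    doy <- doy_no_leap_safe(out$date)
    det <- sc$temp_mean +
      sc$temp_seasonal_amplitude *
        cos(2 * pi * (doy + out$hour / 24 - sc$temp_seasonal_phase) / 365) +
      sc$temp_diurnal_amplitude *
        cos(2 * pi * (out$hour - sc$temp_diurnal_phase) / 24)
    noise <- numeric(nrow(out))
    i0 <- 1
    for (b in blocks) {
      nb <- nrow(b)
      e <- stats::rnorm(nb, 0, sc$noise_sd)
      x <- stats::filter(e, sc$noise_ar, method = "recursive",
                         init = stats::rnorm(1, 0, stat_sd))
      noise[i0:(i0 + nb - 1)] <- as.numeric(x)
      i0 <- i0 + nb
    }
    out$temp_mean <- det
    out$temp <- det + noise
    rownames(out) <- NULL
    return(out)
  }
  dates <- seq(as.Date(sprintf("%d-01-01", min(sc$years))),
               as.Date(sprintf("%d-12-31", max(sc$years))), by = "day")
  dates <- dates[format(dates, "%m-%d") != "02-29"]
  doy <- doy_no_leap(dates)
  det <- sc$temp_mean + sc$temp_seasonal_amplitude *
    cos(2 * pi * (doy - sc$temp_seasonal_phase) / 365)
  e <- stats::rnorm(length(dates), 0, sc$noise_sd)
  noise <- as.numeric(stats::filter(e, sc$noise_ar, method = "recursive",
                                    init = stats::rnorm(1, 0, stat_sd)))
  data.frame(date = dates, temp_mean = det, temp = det + noise)
}

doy_no_leap_safe <- function(dates) {
  feb29 <- format(dates, "%m-%d") == "02-29"
  d <- dates
  d[feb29] <- d[feb29] - 1
  doy_no_leap(d)
}

#' Simulate daily death counts from a scenario and a temperature series
#'
#' The log-rate of day \eqn{i} is the baseline plus a slow linear trend
#' plus the functional exposure term with the scenario's true coefficient:
#' in \code{sflm} mode \eqn{\int_0^{24} x_{i-1}(s)\beta_1(s)ds} with
#' \eqn{x_{i-1}} the previous day's smoothed hourly curve (the term is
#' centred at its across-day mean so the baseline is the mean rate); in
#' \code{fflm} mode the 60-day historical sum of daily temperature
#' anomalies against the true surface, plus a seasonal winter-excess
#' cycle. Counts are Poisson (optionally gamma-mixed) draws from the rate.
#'
#' @param scenario a \code{\link{mort_scenario}}.
#' @param temperature output of \code{\link{simulate_temperature}} for the
#'   same scenario.
#' @param exposure_basis basis used to smooth hourly readings into curves
#'   (\code{sflm} mode; default cubic, dimension 12 on [0, 24]).
#' @return data frame with columns \code{date}, \code{count}; the true
#'   log-rate, the uncentred functional term and (sflm mode) the exposure
#'   curves are attached as attributes \code{"log_rate"},
#'   \code{"functional_term"} and \code{"exposures"}.
#' @export
simulate_counts <- function(scenario, temperature, exposure_basis = NULL) {
  stopifnot(inherits(scenario, "mort_scenario"))
  sc <- scenario
  set.seed(sc$seed + 1000003L)
  if (sc$mode == "sflm") {
    if (is.null(exposure_basis)) exposure_basis <- fd_basis(c(0, 24), 8L)
    curves <- fd_smooth_by_day(temperature, exposure_basis)
    all_days <- as.Date(rownames(curves$coefs))
    # response days: those whose previous day also has a curve
    resp <- all_days[match(all_days - 1, all_days, nomatch = 0) > 0]
    prev_idx <- match(resp - 1, all_days)
    exposures <- fd_sample(exposure_basis,
                           curves$coefs[prev_idx, , drop = FALSE],
                           labels = as.character(resp))
    G <- gram_matrix(exposure_basis, sc$true_beta1$basis)
    term <- drop(exposures$coefs %*% G %*% t(sc$true_beta1$coefs))
    u <- if (length(resp) > 1)
      (as.numeric(resp) - as.numeric(resp[1])) /
        (as.numeric(resp[length(resp)]) - as.numeric(resp[1])) else 0.5
    log_rate <- sc$baseline_log_rate + sc$trend_amplitude * (2 * u - 1) +
      (term - mean(term))
    if (any(log_rate > 10))
      stop(sprintf("log-rate overflow (max %.2f > 10): scenario produces unphysical rates",
                   max(log_rate)))
    counts <- draw_counts(exp(log_rate), sc$overdispersion)
    out <- data.frame(date = resp, count = counts)
    attr(out, "log_rate") <- log_rate
    attr(out, "functional_term") <- term
    attr(out, "exposures") <- exposures
    return(out)
  }
  doy <- doy_no_leap(temperature$date)
  yr <- as.integer(format(temperature$date, "%Y"))
  anom <- temperature$temp - temperature$temp_mean
  n <- nrow(temperature)
  # historical sum: term(i) = sum_{l=0}^{L} anom(i-l) * beta1(t_i - l, t_i)
  L <- sc$true_beta1$max_lag
  term <- numeric(n)
  for (l in 0:L) {
    idx <- (l + 1):n
    s_val <- doy[idx] - l
    ok <- s_val >= 0.5          # truncate the window at the year start
    w <- numeric(length(idx))
    if (any(ok))
      w[ok] <- eval_surface_points(sc$true_beta1, s_val[ok] - 0.5, doy[idx][ok] - 0.5)
    term[idx] <- term[idx] + anom[idx - l] * w
  }
  u <- (seq_len(n) - 1) / (n - 1)
  log_rate <- sc$baseline_log_rate + sc$trend_amplitude * (1 - 2 * u) +
    sc$mort_seasonal_amplitude * cos(2 * pi * (doy - 25) / 365) + term
  if (any(log_rate > 10))
    stop(sprintf("log-rate overflow (max %.2f > 10): scenario produces unphysical rates",
                 max(log_rate)))
  counts <- draw_counts(exp(log_rate), sc$overdispersion)
  out <- data.frame(date = temperature$date, count = counts)
  attr(out, "log_rate") <- log_rate
  attr(out, "functional_term") <- term
  out
}

draw_counts <- function(rate, overdispersion) {
  if (!is.null(overdispersion))
    rate <- rate * stats::rgamma(length(rate), shape = overdispersion,
                                 rate = overdispersion)
  stats::rpois(length(rate), rate)
}

# pointwise surface values beta1(s_i, t_i) (vectorized over pairs)
eval_surface_points <- function(surface, s, t) {
  Bs <- eval_basis(surface$s_basis, s)
  Bt <- eval_basis(surface$t_basis, t)
  v <- rowSums((Bs %*% surface$coefs) * Bt)
  v[s > t | s < t - surface$max_lag] <- 0
  v
}

# smooth one hourly data frame (date, hour, temp) into per-day curves
fd_smooth_by_day <- function(hourly, basis) {
  days <- split(hourly, hourly$date)
  Y <- t(vapply(days, function(d) d$temp[order(d$hour)], numeric(24)))
  pos <- sort(unique(hourly$hour))
  fd_smooth(Y, basis, positions = pos, labels = names(days))
}

#' Generate a complete synthetic dataset for the daily (SFLM) application
#'
#' Convenience wrapper: simulates hourly summer temperature, smooths it
#' into daily exposure curves, simulates counts, and returns everything
#' the scalar-on-function model and its baselines need.
#'
#' @param scenario an \code{sflm}-mode \code{\link{mort_scenario}}.
#' @param n_days optionally truncate to the first \code{n_days} response
#'   days (e.g. 500).
#' @param exposure_basis basis for the exposure curves.
#' @return list with \code{hourly} (data frame), \code{counts} (data
#'   frame), \code{exposures} (\code{fd_sample} aligned with
#'   \code{counts}, each curve the previous day's temperature),
#'   \code{scenario}.
#' @export
synth_sflm_dataset <- function(scenario, n_days = NULL, exposure_basis = NULL) {
  stopifnot(scenario$mode == "sflm")
  hourly <- simulate_temperature(scenario)
  counts <- simulate_counts(scenario, hourly, exposure_basis)
  exposures <- attr(counts, "exposures")
  if (!is.null(n_days)) {
    if (n_days > nrow(counts))
      stop(sprintf("scenario yields only %d response days", nrow(counts)))
    keep <- seq_len(n_days)
    lr <- attr(counts, "log_rate")[keep]
    ft <- attr(counts, "functional_term")[keep]
    exposures <- fd_sample(exposures$basis, exposures$coefs[keep, , drop = FALSE],
                           exposures$labels[keep])
    counts <- counts[keep, ]
    attr(counts, "log_rate") <- lr
    attr(counts, "functional_term") <- ft
  }
  attr(counts, "exposures") <- NULL
  list(hourly = hourly, counts = counts, exposures = exposures,
       scenario = scenario)
}

#' Generate a complete synthetic dataset for the annual (FFLM) application
#'
#' Simulates a daily temperature series and Poisson counts over whole
#' years, and smooths both into annual curves (temperature on a
#' dimension-40 basis that tracks the measurements closely; log-mortality
#' rates on a dimension-16 basis that treats day-to-day count variation
#' as noise).
#'
#' @param scenario an \code{fflm}-mode \code{\link{mort_scenario}}.
#' @param temp_basis,mort_basis annual bases for the two curve families.
#' @return list with \code{daily} (data frame \code{date}, \code{temp},
#'   \code{count}), \code{temperature} and \code{log_mortality}
#'   (\code{fd_sample}s, one curve per year), \code{scenario}.
#' @export
synth_fflm_dataset <- function(scenario, temp_basis = NULL, mort_basis = NULL) {
  stopifnot(scenario$mode == "fflm")
  if (is.null(temp_basis)) temp_basis <- fd_basis(c(0, 365), 36L)
  daily_t <- simulate_temperature(scenario)
  counts <- simulate_counts(scenario, daily_t)
  daily <- data.frame(date = daily_t$date, temp = daily_t$temp,
                      count = counts$count)
  temperature <- annual_curves(daily$temp, daily$date, temp_basis)
  log_mortality <- log_rate_curves(daily$count, daily$date, mort_basis)
  list(daily = daily, temperature = temperature,
       log_mortality = log_mortality, scenario = scenario)
}
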