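make_recovery_data <- function(seed = 2, n_days = 500) {
  sc <- mort_scenario("sflm", seed = seed, years = 2007:2012,
                      true_beta1 = default_beta1_curve(amplitude = 1))
  synth_sflm_dataset(sc, n_days = n_days)
}

test_that("functional design columns match a Riemann integral oracle", {
  set.seed(31)
  ds <- make_recovery_data(n_days = 30)
  fit <- sflm(ds$counts$count, ds$counts$date, ds$exposures)
  cb <- fit$coef_basis
  Z <- ds$exposures$coefs %*% fit$cross_gram
  h <- 24 / 20000
  x <- (seq_len(20000) - 0.5) * h
  Bx <- eval_basis(ds$exposures$basis, x)
  Bb <- eval_basis(cb, x)
  for (i in c(1, 13, 30)) {
    oracle <- colSums(drop(Bx %*% ds$exposures$coefs[i, ]) * Bb) * h
    expect_lt(max(abs(Z[i, ] - oracle)) / max(abs(oracle)), 1e-6)
  }
})

test_that("SFLM recovers a known functional coefficient and rejects a null one", {
  ds <- make_recovery_data(seed = 2)
  fit <- sflm(ds$counts$count, ds$counts$date, ds$exposures)
  g <- seq(0, 24, length.out = 100)
  truth <- sin(2 * pi * g / 24) / 24
  expect_gt(cor(drop(eval_fd(fit$beta1, g)), truth), 0.95)

  # residual identity holds exactly
  expect_equal(fit$fitted_log + fit$residuals, fit$log_responses,
               tolerance = 1e-12)

  # null scenario: beta1 ~ 0 relative to the effect fit (20 replicates)
  null_norms <- vapply(1:20, function(s) {
    sc0 <- mort_scenario("sflm", seed = 100 + s, years = 2007:2012,
                         true_beta1 = fd_sample(fd_basis(c(0, 24), 8L),
                                                matrix(0, 1, 12)))
    ds0 <- synth_sflm_dataset(sc0, n_days = 500)
    f0 <- sflm(ds0$counts$count, ds0$counts$date, ds0$exposures)
    sqrt(mean(eval_fd(f0$beta1, g)^2))
  }, numeric(1))
  effect_norm <- sqrt(mean(eval_fd(fit$beta1, g)^2))
  expect_lt(median(null_norms), 0.25 * effect_norm)
})

test_that("adding a constant to the log response shifts only the intercept", {
  ds <- make_recovery_data(n_days = 120)
  f1 <- sflm(ds$counts$count, ds$counts$date, ds$exposures)
  # tripling counts adds log(3) to every log response
  f2 <- sflm(ds$counts$count * 3, ds$counts$date, ds$exposures)
  expect_equal(f2$beta0 - f1$beta0, log(3), tolerance = 1e-8)
  expect_equal(f2$beta1$coefs, f1$beta1$coefs, tolerance = 1e-8)
})

test_that("SFLM validates its inputs", {
  ds <- make_recovery_data(n_days = 60)
  expect_error(sflm(ds$counts$count[-1], ds$counts$date[-1], ds$exposures),
               "counts.*curves|curves")
  expect_error(sflm(rep(0, 60), ds$counts$date, ds$exposures), "zero")
  expect_error(sflm(ds$counts$count - 100, ds$counts$date, ds$exposures),
               "non-negative")
  bad_basis <- fd_basis(c(0, 23), 8L)
  expect_error(sflm(ds$counts$count, ds$counts$date, ds$exposures,
                    coef_basis = bad_basis), "domain")
})

test_that("prediction reproduces training fits, is linear, and guards extrapolation", {
  ds <- make_recovery_data(n_days = 200)
  fit <- sflm(ds$counts$count, ds$counts$date, ds$exposures)
  p <- predict(fit, ds$exposures, ds$counts$date)
  expect_equal(p, exp(fit$fitted_log), tolerance = 1e-12)

  # doubling a curve doubles its functional contribution on the log scale
  ex2 <- fd_sample(ds$exposures$basis, 2 * ds$exposures$coefs)
  func1 <- log(predict(fit, ds$exposures, ds$counts$date)) -
    log(predict(fit, fd_sample(ds$exposures$basis, 0 * ds$exposures$coefs),
                ds$counts$date))
  func2 <- log(predict(fit, ex2, ds$counts$date)) -
    log(predict(fit, fd_sample(ds$exposures$basis, 0 * ds$exposures$coefs),
                ds$counts$date))
  expect_equal(func2, 2 * func1, tolerance = 1e-10)

  far <- max(ds$counts$date) + 400
  ex1 <- fd_sample(ds$exposures$basis, ds$exposures$coefs[1, , drop = FALSE])
  expect_error(predict(fit, ex1, far), "knot-spacing|extrapolat")
  expect_silent(predict(fit, ex1, far, trend = "clamp"))
})

test_that("held-out predictions beat the training mean when an effect exists", {
  ds <- make_recovery_data(seed = 7)
  tr <- 1:400; te <- 401:500
  fit <- sflm(ds$counts$count[tr], ds$counts$date[tr],
              fd_sample(ds$exposures$basis, ds$exposures$coefs[tr, ]))
  p <- predict(fit, fd_sample(ds$exposures$basis, ds$exposures$coefs[te, ]),
               ds$counts$date[te], trend = "clamp")
  expect_lt(rmse(p, ds$counts$count[te]),
            rmse(rep(mean(ds$counts$count[tr]), 100), ds$counts$count[te]))
})

test_that("large smoothing drives beta1 toward its penalty null space (a line)", {
  ds <- make_recovery_data(n_days = 300)
  P <- penalty_matrix(fd_basis(c(0, 24), 8L), 2)
  rough <- vapply(c(1, 1e3, 1e6, 1e9), function(lam) {
    f <- sflm(ds$counts$count, ds$counts$date, ds$exposures, lambda = lam)
    drop(f$beta1$coefs %*% P %*% t(f$beta1$coefs))
  }, numeric(1))
  expect_true(all(diff(rough) < 1e-12))
})

test_that("wild bootstrap bands are reproducible, degenerate without residuals, and default to 500 replicates", {
  ds <- make_recovery_data(n_days = 150)
  fit <- sflm(ds$counts$count, ds$counts$date, ds$exposures)
  b1 <- wild_bootstrap_band(fit, n_bootstrap = 100, seed = 9)
  b2 <- wild_bootstrap_band(fit, n_bootstrap = 100, seed = 9)
  expect_identical(b1, b2)
  b3 <- wild_bootstrap_band(fit, n_bootstrap = 100, seed = 10)
  expect_false(identical(b1$lower, b3$lower))
  expect_true(all(b1$lower <= b1$upper))
  expect_equal(formals(wild_bootstrap_band)$n_bootstrap, 500L)
  expect_warning(wild_bootstrap_band(fit, n_bootstrap = 20, seed = 1),
                 "unstable")

  # zero residuals: every replicate equals the point estimate
  fit0 <- fit
  fit0$residuals <- rep(0, length(fit$residuals))
  b0 <- wild_bootstrap_band(fit0, n_bootstrap = 50, seed = 3)
  expect_equal(b0$lower, b0$point_estimate, tolerance = 1e-8)
  expect_equal(b0$upper, b0$point_estimate, tolerance = 1e-8)
})
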