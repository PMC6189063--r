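test_that("the historical surface has exact triangular band support", {
  surf <- default_beta1_surface()
  # s in the future of t, or more than max_lag before it -> exactly 0
  expect_identical(drop(eval_surface(surf, 100, 50)), 0)
  expect_identical(drop(eval_surface(surf, 10, 200)), 0)
  expect_true(abs(drop(eval_surface(surf, 190, 200))) > 0)
  sg <- seq(0, 365, by = 7); tg <- seq(0, 365, by = 11)
  M <- eval_surface(surf, sg, tg)
  off <- outer(sg, tg, function(s, t) s > t | s < t - 60)
  expect_true(all(M[off] == 0))
  # masked-out tensor coefficients are exactly zero
  expect_true(all(surf$coefs[!surf$mask] == 0))
  expect_error(hist_surface(surf$s_basis, surf$t_basis, surf$coefs,
                            max_lag = -1), "max_lag")
  expect_error(hist_surface(surf$s_basis, surf$t_basis, surf$coefs,
                            max_lag = 400), "max_lag")
})

test_that("historical-integral design entries match a dense Riemann oracle", {
  set.seed(41)
  temp_basis <- fd_basis(c(0, 365), 20L)
  s_basis <- fd_basis(c(0, 365), 8L)
  tpts <- c(30.5, 181.5, 340.5)  # includes a truncated window (t < 60)
  Q <- fdamort:::window_cross_grams(temp_basis, s_basis, tpts, 60)
  cf <- rnorm(temp_basis$dimension)
  for (k in seq_along(tpts)) {
    t <- tpts[k]
    a <- max(0, t - 60)
    nr <- 50000
    h <- (t - a) / nr
    x <- a + (seq_len(nr) - 0.5) * h
    xv <- drop(eval_basis(temp_basis, x) %*% cf)
    oracle <- colSums(xv * eval_basis(s_basis, x)) * h
    got <- drop(cf %*% Q[[k]])
    expect_lt(max(abs(got - oracle)) / max(abs(oracle)), 1e-6)
  }
})

fflm_recovery <- function(seed = 3) {
  sc <- mort_scenario("fflm", seed = seed)
  ds <- synth_fflm_dataset(sc)
  list(sc = sc, ds = ds, fit = fflm(ds$log_mortality, ds$temperature))
}

test_that("FFLM recovers a known banded surface at 31 years and nulls a zero one", {
  r <- fflm_recovery(seed = 3)
  sg <- seq(0, 365, by = 5); tg <- sg
  inband <- outer(sg, tg, function(s, t) s <= t & s >= t - 60)
  Mh <- eval_surface(r$fit$beta1, sg, tg)
  Mt <- eval_surface(r$sc$true_beta1, sg, tg)
  expect_gt(cor(Mh[inband], Mt[inband]), 0.9)

  # fitted + residual curves reproduce the response on the grid exactly
  expect_equal(r$fit$fitted_grid + r$fit$residual_grid, r$fit$response_grid,
               tolerance = 1e-12)

  # null surface: Frobenius norm well below the effect fit's
  sc0 <- mort_scenario("fflm", seed = 104,
                       true_beta1 = default_beta1_surface(amplitude = 0))
  ds0 <- synth_fflm_dataset(sc0)
  f0 <- fflm(ds0$log_mortality, ds0$temperature)
  expect_lt(norm(f0$beta1$coefs, "F"), 0.2 * norm(r$fit$beta1$coefs, "F"))
})

test_that("sign pattern of the heatmap table matches the generating surface in band", {
  r <- fflm_recovery(seed = 3)
  tab <- surface_heatmap_table(r$fit, s_grid = seq(0, 365, by = 10),
                               t_grid = seq(0, 365, by = 10))
  expect_equal(nrow(tab), 37 * 37)
  truth <- surface_heatmap_table(r$sc$true_beta1, seq(0, 365, by = 10),
                                 seq(0, 365, by = 10))
  inband <- tab$s <= tab$t & tab$s >= tab$t - 60 & abs(truth$value) > 1e-10
  expect_gt(mean(sign(tab$value[inband]) == sign(truth$value[inband])), 0.85)
  # all off-band entries exactly zero
  expect_true(all(tab$value[tab$s > tab$t | tab$s < tab$t - 60] == 0))
})

test_that("FFLM predictions reproduce training fits and are linear in exposure", {
  r <- fflm_recovery(seed = 5)
  fit <- r$fit; ds <- r$ds
  pm <- predict(fit, ds$temperature, seq_len(fit$n_years))
  expect_equal(attr(pm, "log"), fit$fitted_grid, tolerance = 1e-8)
  expect_true(all(pm > 0))
  expect_equal(dim(pm), c(31L, 365L))
  expect_length(discretize_predictions(pm), 31 * 365)

  # +1 degC uniform shift changes the log-prediction by the band integral
  shift <- fd_smooth(matrix(rep(1, 100), 1), ds$temperature$basis,
                     positions = seq(0, 365, length.out = 100))
  tshift <- fd_sample(ds$temperature$basis,
                      sweep(ds$temperature$coefs[1, , drop = FALSE], 2,
                            -shift$coefs[1, ]))
  p1 <- attr(predict(fit, fd_sample(ds$temperature$basis,
                                    ds$temperature$coefs[1, , drop = FALSE]), 1),
             "log")
  p2 <- attr(predict(fit, tshift, 1), "log")
  band_int <- vapply(seq_along(fit$t_grid), function(ti)
    sum(drop(shift$coefs %*% fit$Q[[ti]]) *
        (fit$beta1$coefs %*% fit$Bt[ti, ])), numeric(1))
  expect_equal(drop(p2 - p1), band_int, tolerance = 1e-8)

  expect_error(predict(fit, ds$temperature, rep(40, 31)), "year index")
})

test_that("stronger penalties monotonically flatten the in-band surface", {
  r <- fflm_recovery(seed = 2)
  ds <- r$ds
  Ps <- penalty_matrix(fd_basis(c(0, 365), 8L), 2)
  rough <- vapply(c(1e2, 1e4, 1e6, 1e8), function(lam) {
    f <- fflm(ds$log_mortality, ds$temperature, lambda = c(lam, lam))
    C <- f$beta1$coefs
    sum(diag(t(C) %*% Ps %*% C)) + sum(diag(C %*% Ps %*% t(C)))
  }, numeric(1))
  expect_true(all(diff(rough) < 1e-10))
})

test_that("FFLM validates inputs", {
  r <- fflm_recovery(seed = 2)
  ds <- r$ds
  short <- fd_sample(ds$temperature$basis, ds$temperature$coefs[1:10, ])
  expect_error(fflm(ds$log_mortality, short), "curves")
  expect_error(fflm(ds$log_mortality, ds$temperature, max_lag = 0), "max_lag")
  expect_error(fflm(ds$log_mortality, ds$temperature, max_lag = 700), "max_lag")
})

test_that("log-rate smoothing clips at the floor and annual curves need leap-free dates", {
  set.seed(9)
  dates <- seq(as.Date("2001-01-01"), as.Date("2002-12-31"), by = "day")
  counts <- rpois(length(dates), 1.5)  # small counts: raw rate can dip near 0
  lr <- log_rate_curves(counts, dates)
  expect_s3_class(lr, "fd_sample")
  expect_equal(nrow(lr$coefs), 2)
  grid <- seq(0.5, 364.5, length.out = 200)
  expect_true(all(eval_fd(lr, grid) >= log(0.1) - 0.35))

  leap <- seq(as.Date("2004-01-01"), as.Date("2004-12-31"), by = "day")
  expect_error(annual_curves(rnorm(366), leap, fd_basis(c(0, 365), 8L)),
               "Feb 29")
})
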