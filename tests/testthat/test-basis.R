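test_that("basis construction places equally spaced knots and gets the dimension right", {
  b <- fd_basis(c(0, 24), 10, order = 4)
  expect_equal(b$dimension, 14)
  expect_equal(b$interior_knots, seq(24 / 11, 24 - 24 / 11, length.out = 10))

  b0 <- fd_basis(c(0, 1), 0, order = 1)
  expect_equal(b0$dimension, 1)
  expect_equal(drop(eval_basis(b0, c(0, 0.4, 1))), c(1, 1, 1))

  expect_error(fd_basis(c(0, Inf), 3), "finite")
  expect_error(fd_basis(c(0, 1), 3, order = 0), "order")
  expect_error(fd_basis(c(1, 0), 3), "upper")
})

test_that("basis functions are non-negative and a partition of unity", {
  set.seed(11)
  for (cfg in list(c(0, 24, 10, 4), c(0, 365, 12, 4), c(-3, 7, 5, 2),
                   c(0, 1, 0, 3), c(2, 9, 7, 5))) {
    b <- fd_basis(cfg[1:2], cfg[3], cfg[4])
    x <- sort(c(b$domain, runif(1000, b$domain[1], b$domain[2])))
    B <- eval_basis(b, x)
    expect_true(all(B >= -1e-14))
    expect_true(all(abs(rowSums(B) - 1) < 1e-12))
  }
})

test_that("evaluation matches an independent Cox-de Boor recursion", {
  set.seed(42)
  b <- fd_basis(c(0, 24), 10, order = 4)
  x <- sort(runif(50, 0, 24))
  expect_lt(max(abs(eval_basis(b, x) - deboor_design(b, x))), 1e-10)

  cf <- matrix(rnorm(2 * b$dimension), 2)
  s <- fd_sample(b, cf)
  expect_lt(max(abs(eval_fd(s, x) - cf %*% t(deboor_design(b, x)))), 1e-10)
})

test_that("curve evaluation is linear in coefficients and refuses extrapolation", {
  b <- fd_basis(c(0, 24), 6)
  z <- fd_sample(b, matrix(0, 1, b$dimension))
  expect_equal(drop(eval_fd(z, c(0, 12, 24))), c(0, 0, 0))
  cst <- fd_sample(b, matrix(3.5, 1, b$dimension))
  expect_equal(drop(eval_fd(cst, seq(0, 24, length.out = 7))),
               rep(3.5, 7), tolerance = 1e-12)
  expect_error(eval_fd(cst, 25), "domain")
  expect_error(eval_fd(cst, -0.1), "domain")
})

test_that("smoothing is an exact projection onto the basis span", {
  set.seed(7)
  b <- fd_basis(c(0, 24), 8)
  truth <- matrix(rnorm(3 * b$dimension), 3)
  grid <- seq(0, 24, length.out = 40)
  Y <- truth %*% t(eval_basis(b, grid))
  fit <- fd_smooth(Y, b, positions = grid)
  expect_equal(fit$coefs, truth, tolerance = 1e-8)
  # projection idempotence: smoothing the smooth returns the same coefficients
  fit2 <- fd_smooth(eval_fd(fit, grid), b, positions = grid)
  expect_equal(fit2$coefs, fit$coefs, tolerance = 1e-8)
})

test_that("a cubic basis reproduces a smooth diurnal sinusoid from 24 hourly readings", {
  hours <- 0:23 + 0.5
  tempc <- 20 + 5 * sin(2 * pi * (hours - 9) / 24)
  b <- fd_basis(c(0, 24), 7)  # dimension 11
  fit <- fd_smooth(matrix(tempc, 1), b, positions = hours)
  grid <- seq(0.5, 23.5, length.out = 200)
  expect_lt(max(abs(eval_fd(fit, grid) - (20 + 5 * sin(2 * pi * (grid - 9) / 24)))),
            0.1)
})

test_that("low-dimension smoothing of noisy counts reduces variance", {
  set.seed(21)
  days <- seq(0.5, 364.5)
  raw <- 17 + 3 * cos(2 * pi * days / 365) + rnorm(365, 0, 4)
  b <- fd_basis(c(0, 365), 8)
  fit <- fd_smooth(matrix(raw, 1), b, positions = days)
  expect_lt(var(drop(eval_fd(fit, days))), var(raw))
})

test_that("smoothing validates point counts, rank and labels offending curves", {
  b <- fd_basis(c(0, 24), 6)  # dimension 10
  few <- list(day1 = cbind(seq(0, 24, length.out = 5), rnorm(5)))
  expect_error(fd_smooth(few, b), "day1")
  expect_error(fd_smooth(matrix(rnorm(5), 1), b, positions = seq(0, 24, length.out = 5)),
               "fewer|dimension")
  # 12 points all in [0, 2]: several basis functions unseen -> rank deficient
  clump <- list(bad = cbind(seq(0, 2, length.out = 12), rnorm(12)))
  expect_error(fd_smooth(clump, b), "rank")
})

test_that("LOO-CV hat-matrix shortcut equals brute-force refitting", {
  set.seed(3)
  x <- sort(runif(30, 0, 24))
  y <- sin(x / 3) + rnorm(30, 0, 0.2)
  cand <- c(2, 4)
  res <- select_knots_loocv(list(cbind(x, y)), c(0, 24), 4, cand)
  for (ci in seq_along(cand)) {
    b <- fd_basis(c(0, 24), cand[ci])
    press <- vapply(seq_along(x), function(l) {
      cf <- qr.coef(qr(eval_basis(b, x[-l])), y[-l])
      (y[l] - sum(eval_basis(b, x[l]) * cf))^2
    }, numeric(1))
    expect_equal(res$cv_scores$score[ci], mean(press), tolerance = 1e-8)
  }
})

test_that("knot selection prefers the true small basis and resists overfitting noise", {
  set.seed(5)
  grid <- seq(0, 24, length.out = 30)
  # exactly in the span of the 1-knot cubic basis, no noise -> 1 knot wins
  # (larger candidates chosen so their knot grids do not nest the true knot)
  b1 <- fd_basis(c(0, 24), 1)
  Y <- matrix(rnorm(b1$dimension), 1) %*% t(eval_basis(b1, grid))
  res <- select_knots_loocv(Y, c(0, 24), 4, c(1, 6, 10), positions = grid)
  expect_equal(res$best_count, 1)
  expect_lt(res$cv_scores$score[1], 1e-16)

  # pure white noise around a constant: majority of replicates prefer 0 knots
  wins <- replicate(50, {
    Yn <- matrix(rnorm(30, 10, 1), 1)
    select_knots_loocv(Yn, c(0, 24), 4, c(0, 8), positions = grid)$best_count
  })
  expect_gt(mean(wins == 0), 0.5)
  expect_error(select_knots_loocv(Y, c(0, 24), 4, integer(0), positions = grid),
               "empty|not be")
})

test_that("Gram matrices match a dense Riemann oracle and are PSD", {
  set.seed(13)
  b1 <- fd_basis(c(0, 1), 0, order = 1)
  expect_equal(gram_matrix(b1), matrix(1, 1, 1), tolerance = 1e-12)

  configs <- list(c(0, 24, 10, 4), c(0, 365, 12, 4), c(0, 10, 4, 2),
                  c(-1, 1, 6, 3), c(0, 24, 0, 4))
  for (cfg in configs) {
    b <- fd_basis(cfg[1:2], cfg[3], cfg[4])
    G <- gram_matrix(b)
    R <- riemann_gram(b)
    expect_lt(max(abs(G - R)) / max(abs(R)), 1e-6)
    expect_gt(min(eigen(G, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
  }
  # PSD via inner products
  b <- fd_basis(c(0, 24), 10)
  for (i in 1:100) {
    f <- fd_sample(b, matrix(rnorm(b$dimension), 1))
    expect_gte(inner_product(f, f), 0)
  }
  b2 <- fd_basis(c(0, 23), 10)
  expect_error(inner_product(fd_sample(b, matrix(0, 1, 14)),
                             fd_sample(b2, matrix(0, 1, 14))), "bases")
})

test_that("cross-Gram between two different bases matches the Riemann oracle", {
  ba <- fd_basis(c(0, 24), 9, order = 4)
  bb <- fd_basis(c(0, 24), 5, order = 4)
  J <- gram_matrix(ba, bb)
  R <- riemann_gram(ba, bb)
  expect_lt(max(abs(J - R)) / max(abs(R)), 1e-6)
})

test_that("roughness penalty annihilates straight lines and matches a Riemann oracle", {
  b <- fd_basis(c(0, 24), 8)
  P <- penalty_matrix(b, 2)
  # coefficients of the linear function u -> 2u + 1 via interpolation
  grid <- seq(0, 24, length.out = 50)
  cl <- qr.coef(qr(eval_basis(b, grid)), 2 * grid + 1)
  expect_lt(abs(drop(t(cl) %*% P %*% cl)), 1e-10)
  expect_equal(P, t(P))
  expect_gt(min(eigen(P, symmetric = TRUE, only.values = TRUE)$values), -1e-10)

  set.seed(19)
  cf <- rnorm(b$dimension)
  quad <- drop(t(cf) %*% P %*% cf)
  f2 <- function(u) drop(eval_basis(b, u, deriv = 2) %*% cf)^2
  expect_lt(abs(quad - riemann(f2, 0, 24)) / quad, 1e-5)

  expect_error(penalty_matrix(b, 4), "derivative_order")
})
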