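test_that("negative-log transform and cycle-fraction time axis", {
  v <- array(1, c(2, 2, 6))
  v[1, 1, ] <- exp(-1)
  st <- frame_stack(v, 25, rbind(c(0, 2), c(2, 4), c(4, 6)))
  ab <- neg_log_transform(st, clamp = 1e-12)
  expect_equal(ab$values[2, 2, ], rep(0, 6))         # -ln 1 = 0
  expect_equal(ab$values[1, 1, ], rep(1, 6))         # -ln e^-1 = 1
  expect_equal(ab$t, c(0, 0.5, 1, 1.5, 2, 2.5))      # k + fraction
})

test_that("zero intensities are clamped and counted", {
  v <- array(0.5, c(1, 1, 6)); v[1, 1, 2] <- 0
  st <- frame_stack(v, 25, rbind(c(0, 2), c(2, 4), c(4, 6)))
  ab <- neg_log_transform(st)
  expect_equal(ab$n_clamped, 1L)
  expect_true(all(is.finite(ab$values)))
})

test_that("design matrix has the documented full-rank basis", {
  t <- (0:23) / 8                                    # 3 cycles, 8 frames each
  X <- harmonic_design_matrix(t)
  expect_equal(nrow(X), 24L)
  expect_equal(ncol(X), 8L)                          # 5 Fourier + 3 spline
  expect_equal(qr(X)$rank, ncol(X))
  ti <- t %in% c(0, 1, 2)
  expect_true(all(abs(X[ti, c("sin1", "sin2")]) < 1e-12))
  expect_true(all(abs(X[ti, c("cos1", "cos2")] - 1) < 1e-12))
  expect_error(harmonic_design_matrix((0:15) / 8), "3 cardiac cycles")
})

test_that("the spline columns reproduce piecewise-linear drift exactly", {
  t <- seq(0, 3 - 1e-9, length.out = 90)
  # continuous piecewise-linear function with kinks at the cycle knots
  f <- ifelse(t < 1, 2 * t, ifelse(t < 2, 2 - (t - 1), 1 + 3 * (t - 2)))
  X <- harmonic_design_matrix(t)
  fit <- lm.fit(X, f)
  expect_lt(max(abs(fit$residuals)), 1e-9)
})

test_that("noiseless in-span signals are recovered near-exactly", {
  t <- (0:74) / 25
  y <- 2 + sin(2 * pi * t)
  f <- fit_harmonic_gls(y, t)
  expect_lt(abs(f$a0 - 2), 1e-6)
  expect_lt(abs(f$b1 - 1), 1e-6)
  expect_lt(max(abs(c(f$a1, f$a2, f$b2, f$spline_coeffs))), 1e-6)
  expect_gt(f$r2_adj, 1 - 1e-6)
})

test_that("GLS with rho fixed at 0 equals the OLS normal equations", {
  set.seed(7)
  t <- (0:59) / 20
  for (i in 1:5) {
    y <- stats::rnorm(60)
    f <- fit_harmonic_gls(y, t, rho = 0)
    X <- harmonic_design_matrix(t)
    beta_ols <- solve(crossprod(X), crossprod(X, y))
    expect_lt(max(abs(f$coefficients - beta_ols)), 1e-8)
  }
})

test_that("the REML fit agrees with an independent GLS implementation", {
  skip_if_not_installed("nlme")
  set.seed(21)
  t <- (0:149) / 25                                  # 6 cycles
  e <- as.numeric(stats::arima.sim(list(ar = 0.5), 150, sd = 0.1))
  y <- 1 + 0.8 * cos(2 * pi * t) + 0.5 * sin(2 * pi * t) + 0.05 * t + e
  f <- fit_harmonic_gls(y, t)
  X <- harmonic_design_matrix(t)
  df <- data.frame(y = y, X[, -1L])
  g <- nlme::gls(y ~ ., data = df, method = "REML",
                 correlation = nlme::corAR1(form = ~1))
  rho_nlme <- as.numeric(stats::coef(g$modelStruct$corStruct,
                                     unconstrained = FALSE))
  expect_lt(abs(f$rho - rho_nlme), 0.01)
  expect_lt(max(abs(f$coefficients - stats::coef(g))), 1e-3)
})

test_that("AR(1) coefficient recovery is unbiased at moderate n", {
  set.seed(33)
  t <- (0:299) / 25                                  # 12 cycles
  rhos <- replicate(20, {
    e <- as.numeric(stats::arima.sim(list(ar = 0.5), 300, sd = 0.05))
    y <- 1 + 0.5 * sin(2 * pi * t) + e
    fit_harmonic_gls(y, t)$rho
  })
  expect_lt(abs(stats::median(rhos) - 0.5), 0.15)
})

test_that("amplitude-phase form reconstructs the sine-cosine form", {
  tt <- seq(0, 1, length.out = 257)
  f <- list(a0 = 0.3, a1 = 0, b1 = 1, a2 = 0, b2 = 0)
  f <- to_amplitude_phase(f)
  expect_equal(f$A1, 1)
  expect_equal(f$phi1, 0)                            # pure sin: phi = 0
  g <- to_amplitude_phase(list(a0 = 0, a1 = 1, b1 = 0, a2 = 0, b2 = 0))
  expect_equal(g$phi1, pi / 2)                       # cos = sin shifted
  set.seed(5)
  for (i in 1:20) {
    h <- to_amplitude_phase(list(a0 = stats::rnorm(1), a1 = stats::rnorm(1),
                                 b1 = stats::rnorm(1), a2 = stats::rnorm(1),
                                 b2 = stats::rnorm(1)))
    expect_lt(max(abs(eval_periodic(h, tt) - eval_amplitude_phase(h, tt))),
              1e-10)
  }
  z <- to_amplitude_phase(list(a0 = 0, a1 = 0, b1 = 0, a2 = 1, b2 = 1))
  expect_equal(z$A1, 0)
  expect_equal(z$phi1, 0)
  expect_true(z$degenerate[["h1"]])
})

test_that("HRWA is the peak-to-trough of the periodic component", {
  f1 <- to_amplitude_phase(list(a0 = 5, a1 = 0, b1 = 1, a2 = 0, b2 = 0))
  expect_lt(abs(hrwa(f1) - 2), 1e-7)
  f2 <- to_amplitude_phase(list(a0 = -1, a1 = 0, b1 = 0, a2 = 0, b2 = 1))
  expect_lt(abs(hrwa(f2) - 2), 1e-7)
  f3 <- to_amplitude_phase(list(a0 = 0, a1 = 1, b1 = 0, a2 = 0.5, b2 = 0))
  grid <- seq(0, 1, length.out = 200001)
  v <- cos(2 * pi * grid) + 0.5 * cos(4 * pi * grid)
  expect_lt(abs(hrwa(f3) - (max(v) - min(v))), 1e-6)
  # invariant to the intercept
  f4 <- f3; f4$a0 <- 100
  expect_equal(hrwa(f4), hrwa(f3))
})

test_that("circularly shifting the series shifts phi1 by -2*pi*delta", {
  t <- (0:74) / 25
  delta <- 7 / 25                                    # shift by 7 frames
  y <- sin(2 * pi * t) + 0.3 * cos(4 * pi * t)
  f0 <- fit_harmonic_gls(y, t)
  yshift <- sin(2 * pi * (t + delta)) + 0.3 * cos(4 * pi * (t + delta))
  f1 <- fit_harmonic_gls(yshift, t)
  dphi <- (f1$phi1 - f0$phi1 - 2 * pi * delta + pi) %% (2 * pi) - pi
  expect_lt(abs(dphi), 1e-3)
})

test_that("parameter estimates tighten as the series grows", {
  set.seed(44)
  err <- vapply(c(75, 300, 1200), function(n) {
    reps <- replicate(8, {
      t <- (0:(n - 1)) / (n / 3)
      e <- as.numeric(stats::arima.sim(list(ar = 0.4), n, sd = 0.3))
      y <- 1 + 0.8 * sin(2 * pi * t) + 0.4 * cos(2 * pi * t) + e
      f <- fit_harmonic_gls(y, t)
      abs(f$b1 - 0.8) + abs(f$a1 - 0.4)
    })
    mean(reps)
  }, numeric(1))
  expect_lt(err[3L], err[1L])
})
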