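test_that("phase profiles are unwrapped and origin-normalized", {
  pr <- build_phase_profile(fits_df(rep(1.3, 5)))
  expect_equal(pr$phase, rep(0, 5))

  pr2 <- build_phase_profile(fits_df(c(0.1, 3.0, -3.0)))
  expect_equal(pr2$phase, c(0, 2.9, -3.0 + 2 * pi - 0.1), tolerance = 1e-12)
  expect_true(all(abs(diff(pr2$phase + c(0.1, 0.1, 0.1))) <= pi + 1e-12))
})

test_that("non-converged fits are excluded with a warning, too many is an
           error", {
  f <- fits_df(seq(0, -1, length.out = 10),
               converged = c(FALSE, rep(TRUE, 9)))
  expect_warning(pr <- build_phase_profile(f), "non-converged")
  expect_equal(length(pr$phase), 9L)
  f2 <- fits_df(seq(0, -1, length.out = 10),
                converged = rep(c(FALSE, TRUE), 5))
  expect_error(suppressWarnings(build_phase_profile(f2)), "processing error")
})

test_that("loess smoothing reproduces low-order polynomials exactly", {
  d <- seq(0, 1, length.out = 40)
  lin <- build_phase_profile(fits_df(0.3 - 2 * d, d = d))
  lin <- smooth_phase(lin)
  expect_lt(max(abs(lin$loess_phase - lin$phase)), 1e-6)
  quad <- build_phase_profile(fits_df(1 - 3 * d + 2 * d^2, d = d))
  quad <- smooth_phase(quad)
  expect_lt(max(abs(quad$loess_phase - quad$phase)), 1e-6)
  expect_error(smooth_phase(build_phase_profile(fits_df(c(0, -1, -2)))),
               "at least 5")
})

test_that("loess reduces noise around the true profile", {
  set.seed(9)
  d <- seq(0, 1, length.out = 60)
  truth <- -2 * d + 1.5 * pmax(d - 0.5, 0)
  noisy <- truth + stats::rnorm(60, 0, 0.1)
  pr <- smooth_phase(build_phase_profile(fits_df(noisy, d = d)))
  shift <- noisy[1L]                      # profile was origin-normalized
  expect_lt(stats::sd(pr$loess_phase - (truth - shift)),
            stats::sd(pr$phase - (truth - shift)))
})

test_that("segment selection finds the first peak-to-trough interval", {
  d <- seq(0, 1, length.out = 41)
  # rises to a peak at d=0.25, falls to a trough at d=0.65, rises again
  v <- ifelse(d < 0.25, 2 * d,
              ifelse(d < 0.65, 0.5 - 3 * (d - 0.25), -0.7 + (d - 0.65)))
  pr <- smooth_phase(build_phase_profile(fits_df(v, d = d)))
  seg <- select_segment(pr)
  expect_equal(seg$orientation, "forward")
  expect_lte(abs(seg$start - which.min(abs(d - 0.25))), 1)
  # the asymmetric kink (slopes -3 vs +1) pulls the loess trough slightly
  # toward the shallow side
  expect_lte(abs(seg$end - which.min(abs(d - 0.65))), 2)
})

test_that("a decreasing profile treats the origin as the boundary
           maximum", {
  d <- seq(0, 1, length.out = 41)
  v <- ifelse(d < 0.6, -2 * d, -1.2 + 1.5 * (d - 0.6))
  pr <- smooth_phase(build_phase_profile(fits_df(v, d = d)))
  seg <- select_segment(pr)
  expect_equal(seg$start, 1L)
  expect_lte(abs(seg$end - which.min(abs(d - 0.6))), 1)
  # without the convention there is no qualifying maximum at all
  expect_error(select_segment(pr, boundary_extrema = FALSE),
               "segment undetectable")
})

test_that("monotone profiles raise a segment-undetectable error", {
  d <- seq(0, 1, length.out = 21)
  up <- smooth_phase(build_phase_profile(fits_df(2 * d, d = d)))
  expect_error(select_segment(up), "segment undetectable")
  down <- smooth_phase(build_phase_profile(fits_df(-2 * d, d = d)))
  expect_error(select_segment(down), "segment undetectable")
})

test_that("the HRWA-peak-inside-segment observation is reported as a QC
           flag", {
  d <- seq(0, 1, length.out = 41)
  v <- ifelse(d < 0.5, -d, -0.5 + 0.8 * (d - 0.5))
  hr <- exp(-((d - 0.25) / 0.2)^2)        # HRWA peaks inside [0, 0.5]
  pr <- smooth_phase(build_phase_profile(fits_df(v, d = d, hrwa = hr)))
  expect_true(select_segment(pr)$hrwa_max_inside)
  hr2 <- exp(-((d - 0.9) / 0.1)^2)        # HRWA peaks outside
  pr2 <- smooth_phase(build_phase_profile(fits_df(v, d = d, hrwa = hr2)))
  expect_false(select_segment(pr2)$hrwa_max_inside)
})

test_that("the velocity conversion is exact and correctly signed", {
  d <- seq(0, 0.5, length.out = 21)
  pr <- build_phase_profile(fits_df(-2 * pi * d, d = d))
  est <- estimate_pwv(pr, list(start = 1L, end = 21L), Ts_seconds = 1)
  expect_equal(est$beta, -2 * pi, tolerance = 1e-10)
  expect_equal(est$pwv_mm_per_s, 1, tolerance = 1e-10)
  expect_lt(abs(est$pwv_mm_per_s * est$beta * est$Ts_seconds + 2 * pi),
            1e-12)

  # the scale of the observed median speed: beta = -0.3023 rad/mm at Ts = 1 s
  pr2 <- build_phase_profile(fits_df(-0.3023 * d, d = d))
  est2 <- estimate_pwv(pr2, list(start = 1L, end = 21L), 1)
  expect_equal(est2$pwv_mm_per_s, 20.78, tolerance = 1e-3)
})

test_that("pwv is equivariant to distance scaling and invariant to phase
           offsets", {
  set.seed(2)
  d <- seq(0, 0.4, length.out = 25)
  ph <- -1.7 * d + stats::rnorm(25, 0, 0.01)
  pr <- build_phase_profile(fits_df(ph, d = d))
  est <- estimate_pwv(pr, list(start = 1L, end = 25L), 0.8)
  prk <- pr; prk$distance_mm <- 3 * pr$distance_mm
  estk <- estimate_pwv(prk, list(start = 1L, end = 25L), 0.8)
  expect_equal(estk$beta, est$beta / 3, tolerance = 1e-9)
  expect_equal(estk$pwv_mm_per_s, 3 * est$pwv_mm_per_s, tolerance = 1e-9)
  pro <- pr; pro$phase <- pr$phase + 5
  esto <- estimate_pwv(pro, list(start = 1L, end = 25L), 0.8)
  expect_equal(esto$pwv_mm_per_s, est$pwv_mm_per_s, tolerance = 1e-12)
})

test_that("degenerate segments are rejected", {
  d <- seq(0, 0.5, length.out = 21)
  pr <- build_phase_profile(fits_df(-2 * pi * d, d = d))
  expect_error(estimate_pwv(pr, list(start = 1L, end = 2L), 1), "3 points")
  prz <- build_phase_profile(fits_df(rep(0, 21), d = d))
  expect_error(estimate_pwv(prz, list(start = 1L, end = 21L), 1),
               "infinite-velocity")
  prd <- build_phase_profile(fits_df(c(0, -1, -2), d = c(1, 1, 1) * 0.2))
  expect_error(estimate_pwv(prd, list(start = 1L, end = 3L), 1),
               "degenerate")
  set.seed(1)
  prn <- build_phase_profile(
    fits_df(-2 * pi * d + stats::rnorm(21, 0, 0.01), d = d))
  expect_warning(
    estimate_pwv(prn, list(start = 1L, end = 5L), 1), "short segment")
})
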