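test_that("calibration equates the disc's vertical pixel extent to its
           OCT diameter", {
  m <- matrix(FALSE, 200, 100); m[26:175, 40:60] <- TRUE   # 150 px tall
  expect_equal(calibrate_mm_per_pixel(m, 1.8), 0.012)
  m2 <- matrix(FALSE, 120, 100); m2[11:110, 50] <- TRUE    # 100 px tall
  expect_equal(calibrate_mm_per_pixel(m2, 1.0), 0.01)
  m3 <- matrix(FALSE, 5, 5); m3[3, 3] <- TRUE
  expect_equal(calibrate_mm_per_pixel(m3, 1), 1)
  expect_error(calibrate_mm_per_pixel(matrix(FALSE, 5, 5), 1), "empty")
})

test_that("a horizontal bar skeletonizes to its middle row with unit
           steps", {
  m <- matrix(FALSE, 21, 40); m[10:12, 3:38] <- TRUE
  g <- extract_centreline(m, disc_centre = c(10, 3), mm_per_pixel = 0.01)
  expect_true(all(g$centreline[, 1L] == 10))               # middle row (0-based)
  expect_true(all(abs(diff(g$distances_mm) - 0.01) < 1e-12))
  expect_equal(g$distances_mm[1L], 0)
})

test_that("a 45-degree bar yields sqrt(2) diagonal steps", {
  m <- matrix(FALSE, 40, 40)
  for (i in 3:36) m[(i - 1):(i + 1), i] <- TRUE
  g <- extract_centreline(m, disc_centre = c(3, 3), mm_per_pixel = 0.01)
  expect_true(all(abs(diff(g$distances_mm) - sqrt(2) * 0.01) < 1e-9))
})

test_that("distances are strictly increasing with spacing at most a
           diagonal step", {
  sim <- sim_clean()
  g <- extract_centreline(sim$truth$vein_mask, sim$truth$disc_centre_px,
                          sim$truth$mm_per_pixel)
  expect_true(all(diff(g$distances_mm) > 0))
  expect_true(all(diff(g$distances_mm) <= sqrt(2) * g$mm_per_pixel + 1e-12))
})

test_that("path length is stable under a 90-degree rotation of the mask", {
  sim <- sim_clean()
  m <- sim$truth$vein_mask
  g1 <- extract_centreline(m, sim$truth$disc_centre_px, 0.01)
  m90 <- t(m)[ncol(m):1, ]                                 # rotate 90 deg
  ctr <- sim$truth$disc_centre_px
  ctr90 <- c(ncol(m) - 1 - ctr[2L], ctr[1L])
  g2 <- extract_centreline(m90, ctr90, 0.01)
  expect_lt(abs(max(g1$distances_mm) - max(g2$distances_mm)),
            sqrt(2) * 0.01)
})

test_that("the extracted centreline tracks the simulator's analytic spine
           to better than one pixel", {
  sim <- sim_clean()
  g <- extract_centreline(sim$truth$vein_mask, sim$truth$disc_centre_px,
                          sim$truth$mm_per_pixel)
  sp <- sim$truth$true_spine
  d <- vapply(seq_len(nrow(g$centreline)), function(i) {
    sqrt(min((sp[, 1L] - g$centreline[i, 1L])^2 +
             (sp[, 2L] - g$centreline[i, 2L])^2))
  }, numeric(1))
  expect_lt(mean(d), 1)
})

test_that("clip_to_disc keeps the in-disc prefix and sets L_boundary", {
  m <- matrix(FALSE, 21, 40); m[10:12, 3:38] <- TRUE
  g <- extract_centreline(m, c(10, 3), 0.01,
                          disc_mask = matrix(TRUE, 21, 40))
  gc <- clip_to_disc(g)
  expect_equal(gc$centreline, g$centreline)
  expect_equal(gc$L_boundary_mm, max(g$distances_mm))

  disc <- matrix(FALSE, 21, 40); disc[, 1:20] <- TRUE
  g2 <- clip_to_disc(extract_centreline(m, c(10, 3), 0.01, disc_mask = disc))
  expect_true(all(g2$centreline[, 2L] <= 19))
  expect_equal(g2$L_boundary_mm, max(g2$distances_mm))

  origin_only <- matrix(FALSE, 21, 40); origin_only[11, 4] <- TRUE
  g3 <- clip_to_disc(extract_centreline(m, c(10, 3), 0.01,
                                        disc_mask = origin_only))
  expect_equal(nrow(g3$centreline), 1L)
  expect_equal(g3$L_boundary_mm, 0)
})

test_that("default fixture geometry lands in the observed L_boundary
           range", {
  sim <- sim_clean()
  g <- clip_to_disc(extract_centreline(sim$truth$vein_mask,
                                       sim$truth$disc_centre_px,
                                       sim$truth$mm_per_pixel,
                                       disc_mask = sim$truth$disc_mask))
  expect_gt(g$L_boundary_mm, 0.33)
  expect_lt(g$L_boundary_mm, 0.83)
})
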