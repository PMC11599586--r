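#' Synthetic PPG video configuration
#'
#' Defines the forward model of a pulsating dark vessel on a brighter
#' fundus background, imaged at video rate: the vessel's axial blood-column
#' thickness oscillates as a travelling wave whose temporal phase varies
#' linearly with arc-length (slope `-2*pi/(c*T)` for wave speed `c` and
#' cycle duration `T`); green intensity follows the Beer-Lambert law
#' `background * exp(-absorbance * thickness)`; inter-frame camera jitter,
#' per-frame blur events and temporally autocorrelated (AR(1)) pixel noise
#' are layered on top. Beyond `turn_mm` along the vessel the wave runs in
#' the opposite direction (`return_speed_mm_s`), reproducing the
#' down-then-up distance-phase shape observed in retinal veins and giving
#' the segment-selection step a known turning point.
#'
#' Default geometry (0.01 mm/pixel, disc radius 0.55 mm) puts the
#' centreline-to-boundary path length in the 0.33-0.83 mm range typical of
#' optic-disc vein segments, with phase sampled about every 0.01 mm.
#'
#' @param image_shape `(rows, cols)` of each frame.
#' @param frame_rate_hz frames per second (default 25).
#' @param n_cycles number of cardiac cycles (>= 3).
#' @param cycle_duration_s cycle length in seconds, scalar or per-cycle.
#' @param mm_per_pixel pixel size.
#' @param disc_centre_px,disc_radius_px optic-disc circle, 0-based pixels.
#' @param vessel_control_points n x 2 matrix of 0-based (row, col) control
#'   points of the vessel spine, ordered from the disc centre outward.
#' @param vessel_radius_px baseline vessel radius in pixels.
#' @param wave_speed_mm_s signed wave speed; positive travels away from the
#'   disc centre, negative toward it.
#' @param return_speed_mm_s wave speed beyond the turning point (default:
#'   `-wave_speed_mm_s`, the opposite direction).
#' @param turn_mm arc-length of the turning point (mm); `Inf` disables it.
#' @param pulse_amplitude peak fractional radius oscillation.
#' @param amp_peak_mm,amp_width_mm Gaussian pulsation-amplitude envelope:
#'   peak location and width along the vessel (mm). Maximum pulsation sits
#'   near the disc centre, as observed in retinal veins.
#' @param second_harmonic_fraction relative amplitude of the second
#'   harmonic of the pulse waveform.
#' @param background_intensity fundus intensity inside the disc (unit
#'   scale).
#' @param absorbance_per_mm Beer-Lambert absorbance coefficient.
#' @param texture_sd amplitude of the static smooth background texture
#'   (gives the registration stages features to lock onto).
#' @param noise_sd marginal SD of the additive intensity noise (unit
#'   scale; the default is about one 8-bit count of sensor noise).
#' @param noise_rho temporal AR(1) coefficient of the pixel noise.
#' @param jitter_translation_px,jitter_rotation_deg,jitter_affine per-frame
#'   camera-motion ranges (uniform; frame 0 is never jittered).
#' @param blur_frames list of `c(frame_index_0based, gaussian_sigma)` blur
#'   events.
#' @param quantize_8bit round intensities to 8-bit steps (default TRUE).
#' @param seed RNG seed; rendering is deterministic given the config.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(image_shape = c(144L, 192L),
                              frame_rate_hz = 25,
                              n_cycles = 3L,
                              cycle_duration_s = 0.8,
                              mm_per_pixel = 0.01,
                              disc_centre_px = c(72, 76),
                              disc_radius_px = 55,
                              vessel_control_points =
                                rbind(c(74, 78), c(92, 92), c(112, 106),
                                      c(132, 128), c(142, 150)),
                              vessel_radius_px = 4,
                              wave_speed_mm_s = 20,
                              return_speed_mm_s = NULL,
                              turn_mm = 0.35,
                              pulse_amplitude = 0.15,
                              amp_peak_mm = 0.1,
                              amp_width_mm = 0.4,
                              second_harmonic_fraction = 0.3,
                              background_intensity = 0.85,
                              absorbance_per_mm = 8.5,
                              texture_sd = 0.03,
                              noise_sd = 0.004,
                              noise_rho = 0.3,
                              jitter_translation_px = 0,
                              jitter_rotation_deg = 0,
                              jitter_affine = 0,
                              blur_frames = NULL,
                              quantize_8bit = TRUE,
                              seed = 1L) {
  if (is.null(return_speed_mm_s)) return_speed_mm_s <- -wave_speed_mm_s
  cfg <- as.list(environment())
  stopifnot(cfg$n_cycles >= 3L, cfg$frame_rate_hz > 0, cfg$mm_per_pixel > 0,
            cfg$vessel_radius_px > 0, cfg$absorbance_per_mm > 0,
            abs(cfg$noise_rho) < 1, cfg$wave_speed_mm_s != 0,
            cfg$second_harmonic_fraction >= 0,
            cfg$second_harmonic_fraction < 1)
  if (cfg$pulse_amplitude * (1 + cfg$second_harmonic_fraction) >= 1) {
    stop("config error: pulsation amplitude would drive the blood-column ",
         "thickness negative")
  }
  structure(cfg, class = "simulation_config")
}

## Dense spine samples through the control points (natural splines on
## chord-length parameter), with arc-length (mm) from the first sample.
dense_spine <- function(cfg, step_px = 0.25) {
  cp <- cfg$vessel_control_points
  chord <- c(0, cumsum(sqrt(rowSums(diff(cp)^2))))
  s <- seq(0, max(chord), by = step_px)
  r <- stats::spline(chord, cp[, 1L], xout = s, method = "natural")$y
  c <- stats::spline(chord, cp[, 2L], xout = s, method = "natural")$y
  arc_px <- c(0, cumsum(sqrt(diff(r)^2 + diff(c)^2)))
  list(row = r, col = c, arc_mm = arc_px * cfg$mm_per_pixel)
}

## Per-pixel perpendicular distance to the spine and arc-length of the
## nearest spine sample, computed in chunks to bound memory.
spine_distance_field <- function(cfg, sp, reach) {
  d <- cfg$image_shape
  grid <- as.matrix(expand.grid(r = seq_len(d[1L]) - 1,
                                c = seq_len(d[2L]) - 1))
  n <- nrow(grid)
  r_perp <- rep(Inf, n); arc <- rep(NA_real_, n)
  # only pixels inside the spine bounding box (+reach) can be in the vessel
  box <- grid[, 1L] >= min(sp$row) - reach & grid[, 1L] <= max(sp$row) + reach &
         grid[, 2L] >= min(sp$col) - reach & grid[, 2L] <= max(sp$col) + reach
  cand <- which(box)
  chunk <- 4000L
  for (s in seq(1L, length(cand), by = chunk)) {
    e <- min(s + chunk - 1L, length(cand))
    i <- cand[s:e]
    dr <- outer(grid[i, 1L], sp$row, "-")
    dc <- outer(grid[i, 2L], sp$col, "-")
    d2 <- dr * dr + dc * dc
    j <- max.col(-d2, ties.method = "first")
    r_perp[i] <- sqrt(d2[cbind(seq_along(i), j)])
    arc[i] <- sp$arc_mm[j]
  }
  list(grid = grid, r_perp = r_perp, arc_mm = arc)
}

## Piecewise-linear travelling-wave phase (radians) at arc-length x (mm).
phase_at_arclength <- function(x, cfg, Ts) {
  k1 <- -2 * pi / (cfg$wave_speed_mm_s * Ts)
  k2 <- -2 * pi / (cfg$return_speed_mm_s * Ts)
  ifelse(x <= cfg$turn_mm,
         k1 * x,
         k1 * cfg$turn_mm + k2 * (x - cfg$turn_mm))
}

#' Render a synthetic PPG video with ground truth
#'
#' Executes the forward model described in [simulation_config()] and
#' returns the RGB frame stack together with everything a test needs to
#' judge the pipeline: the exact phase-by-arclength profile (whose slope
#' satisfies `slope = -2*pi/(speed * Ts)` by construction), the true spine,
#' the disc and vein masks, the per-frame camera transforms, the clean
#' green channel and the cycle partition.
#'
#' @param cfg a `simulation_config`.
#' @return list with `rgb` (array rows x cols x 3 x frames, in `[0, 1]`)
#'   and `truth` (list; see Details).
#' @details `truth` contains `true_speed_mm_s`, `Ts_seconds`,
#'   `phase_slope_rad_per_mm`, `turn_mm`, `arc_mm` and
#'   `true_phase_by_arclength` (at the true spine pixels),
#'   `true_spine` (0-based pixel path), `true_transforms` (backward maps
#'   applied to each frame; identity for frame 0), `disc_mask`,
#'   `vein_mask`, `cycle_bounds` (0-based half-open), `mm_per_pixel`,
#'   `disc_vertical_diameter_mm`, `disc_centre_px`, and `green` (the clean
#'   quantized green-channel stack actually embedded in `rgb`).
#' @export
render_video <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  d <- cfg$image_shape
  dur <- rep(cfg$cycle_duration_s, length.out = cfg$n_cycles)
  fpc <- round(dur * cfg$frame_rate_hz)
  n_frames <- sum(fpc)
  ends <- cumsum(fpc)
  cycle_bounds <- cbind(start = c(0L, ends[-length(ends)]), end = ends)
  Ts <- mean(fpc) / cfg$frame_rate_hz

  sp <- dense_spine(cfg)
  R0 <- cfg$vessel_radius_px
  reach <- R0 * (1 + cfg$pulse_amplitude *
                   (1 + cfg$second_harmonic_fraction)) + 1
  fld <- spine_distance_field(cfg, sp, reach)
  corridor <- which(fld$r_perp <= reach)
  x_mm <- fld$arc_mm[corridor]
  rp <- fld$r_perp[corridor]
  A <- cfg$pulse_amplitude *
    exp(-((x_mm - cfg$amp_peak_mm) / cfg$amp_width_mm)^2)
  Phi <- phase_at_arclength(x_mm, cfg, Ts)

  # static scene: dimmer fundus, brighter disc, smooth texture
  rr <- matrix(seq_len(d[1L]) - 1, d[1L], d[2L])
  cc <- matrix(seq_len(d[2L]) - 1, d[1L], d[2L], byrow = TRUE)
  in_disc <- (rr - cfg$disc_centre_px[1L])^2 +
             (cc - cfg$disc_centre_px[2L])^2 <= cfg$disc_radius_px^2
  base <- matrix(0.55, d[1L], d[2L])
  base[in_disc] <- cfg$background_intensity
  tex <- matrix(stats::rnorm(prod(d)), d[1L], d[2L])
  tex <- as.matrix(EBImage::gblur(tex, sigma = 2.5))
  base <- base + cfg$texture_sd * tex / stats::sd(tex)
  base <- pmin(pmax(base, 0.05), 1)

  # per-frame cycle-fraction time
  tfrac <- numeric(n_frames)
  for (k in seq_len(nrow(cycle_bounds))) {
    i <- (cycle_bounds[k, 1L] + 1L):cycle_bounds[k, 2L]
    tfrac[i] <- (k - 1L) + (i - 1L - cycle_bounds[k, 1L]) / fpc[k]
  }

  # camera jitter (frame 0 untouched)
  transforms <- rep(list(diag(3)), n_frames)
  if (n_frames > 1L &&
      (cfg$jitter_translation_px > 0 || cfg$jitter_rotation_deg > 0 ||
       cfg$jitter_affine > 0)) {
    centre <- (d - 1) / 2
    for (i in 2:n_frames) {
      M <- affine_rigid(stats::runif(1, -1, 1) * cfg$jitter_rotation_deg,
                        stats::runif(1, -1, 1) * cfg$jitter_translation_px,
                        stats::runif(1, -1, 1) * cfg$jitter_translation_px,
                        centre)
      if (cfg$jitter_affine > 0) {
        M[1:2, 1:2] <- M[1:2, 1:2] +
          matrix(stats::runif(4, -1, 1) * cfg$jitter_affine, 2, 2)
      }
      transforms[[i]] <- M
    }
  }

  h2 <- cfg$second_harmonic_fraction
  mu <- cfg$absorbance_per_mm
  green <- array(0, c(d, n_frames))
  for (i in seq_len(n_frames)) {
    s <- sin(2 * pi * tfrac[i] + Phi) + h2 * sin(4 * pi * tfrac[i] + 2 * Phi)
    Rt <- R0 * (1 + A * s)
    th_mm <- 2 * sqrt(pmax(Rt^2 - rp^2, 0)) * cfg$mm_per_pixel
    img <- base
    img[fld$grid[corridor, , drop = FALSE] + 1L] <-
      base[fld$grid[corridor, , drop = FALSE] + 1L] * exp(-mu * th_mm)
    if (!identical(transforms[[i]], diag(3))) {
      img <- warp_affine(img, transforms[[i]])
    }
    green[, , i] <- img
  }

  if (!is.null(cfg$blur_frames)) {
    for (bf in cfg$blur_frames) {
      green[, , bf[1L] + 1L] <-
        as.matrix(EBImage::gblur(green[, , bf[1L] + 1L], sigma = bf[2L]))
    }
  }

  if (cfg$noise_sd > 0) {
    # stationary AR(1) over time, independent across pixels
    npx <- prod(d)
    innov_sd <- cfg$noise_sd * sqrt(1 - cfg$noise_rho^2)
    noise <- matrix(0, npx, n_frames)
    noise[, 1L] <- stats::rnorm(npx, 0, cfg$noise_sd)
    for (i in seq_len(n_frames)[-1L]) {
      noise[, i] <- cfg$noise_rho * noise[, i - 1L] +
        stats::rnorm(npx, 0, innov_sd)
    }
    green <- green + array(noise, c(d, n_frames))
  }
  green <- pmin(pmax(green, 0), 1)
  if (cfg$quantize_8bit) green <- round(green * 255) / 255

  red <- pmin(pmax(0.55 + 0.25 * green, 0), 1)
  blue <- 0.3 * green
  rgb <- array(0, c(d, 3L, n_frames))
  rgb[, , 1L, ] <- red
  rgb[, , 2L, ] <- green
  rgb[, , 3L, ] <- blue

  vein_mask <- matrix(FALSE, d[1L], d[2L])
  vein_mask[matrix(fld$grid[fld$r_perp <= R0, ] + 1L, ncol = 2L)] <- TRUE
  spine_px <- unique(cbind(round(sp$row), round(sp$col)))
  spine_arc <- sp$arc_mm[!duplicated(cbind(round(sp$row), round(sp$col)))]
  disc_rows <- range(which(rowSums(in_disc) > 0))
  list(
    rgb = rgb,
    truth = list(
      true_speed_mm_s = cfg$wave_speed_mm_s,
      return_speed_mm_s = cfg$return_speed_mm_s,
      Ts_seconds = Ts,
      phase_slope_rad_per_mm = -2 * pi / (cfg$wave_speed_mm_s * Ts),
      turn_mm = cfg$turn_mm,
      arc_mm = spine_arc,
      true_phase_by_arclength = phase_at_arclength(spine_arc, cfg, Ts),
      true_spine = spine_px,
      true_transforms = transforms,
      disc_mask = in_disc,
      vein_mask = vein_mask,
      cycle_bounds = cycle_bounds,
      mm_per_pixel = cfg$mm_per_pixel,
      disc_vertical_diameter_mm =
        (disc_rows[2L] - disc_rows[1L] + 1L) * cfg$mm_per_pixel,
      disc_centre_px = cfg$disc_centre_px,
      green = green
    )
  )
}

#' Write a deterministic fixture suite to disk
#'
#' Renders small videos at wave speeds 5, 20 and 60 mm/s (spanning the
#' range observed in retinal veins) plus a reversed-direction -20 mm/s
#' case, and writes for each a multi-frame TIFF video, PNG disc/vein
#' masks, a YAML run config and a JSON ground-truth file. Output is
#' byte-identical for a fixed seed.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed; each fixture derives its own sub-seed.
#' @param speeds wave speeds in mm/s.
#' @param ... overrides passed to [simulation_config()].
#' @return invisibly, the fixture directories.
#' @export
make_fixture_suite <- function(dir, seed = 1L, speeds = c(5, 20, 60, -20),
                               ...) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- character(0)
  for (i in seq_along(speeds)) {
    cfg <- simulation_config(wave_speed_mm_s = speeds[i],
                             seed = seed + i, ...)
    sim <- render_video(cfg)
    sub <- file.path(dir, sprintf("speed_%+03d", as.integer(speeds[i])))
    dir.create(sub, showWarnings = FALSE)
    n <- dim(sim$rgb)[4L]
    frames <- lapply(seq_len(n), function(k) {
      aperm(sim$rgb[, , , k], c(1, 2, 3))
    })
    tiff::writeTIFF(frames, file.path(sub, "video.tif"),
                    bits.per.sample = 16L)
    png::writePNG(sim$truth$disc_mask * 1, file.path(sub, "disc_mask.png"))
    png::writePNG(sim$truth$vein_mask * 1, file.path(sub, "vein_mask.png"))
    yaml::write_yaml(list(
      video = "video.tif",
      disc_mask = "disc_mask.png",
      vein_mask = "vein_mask.png",
      frame_rate_hz = cfg$frame_rate_hz,
      cycle_bounds = apply(sim$truth$cycle_bounds, 1L, as.list),
      disc_vertical_diameter_mm = sim$truth$disc_vertical_diameter_mm,
      seed = cfg$seed
    ), file.path(sub, "config.yaml"))
    jsonlite::write_json(list(
      true_speed_mm_s = sim$truth$true_speed_mm_s,
      Ts_seconds = sim$truth$Ts_seconds,
      phase_slope_rad_per_mm = sim$truth$phase_slope_rad_per_mm,
      turn_mm = sim$truth$turn_mm,
      mm_per_pixel = sim$truth$mm_per_pixel
    ), file.path(sub, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
    out <- c(out, sub)
  }
  invisible(out)
}
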