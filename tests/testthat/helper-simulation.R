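# Shared simulation fixtures, rendered once per test run and cached.

.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(name, cfg) {
  if (!exists(name, envir = .sim_cache)) {
    assign(name, render_video(cfg), envir = .sim_cache)
  }
  get(name, envir = .sim_cache)
}

# noiseless, jitter-free scene at the default 20 mm/s
sim_clean <- function() {
  cached_sim("clean", simulation_config(noise_sd = 0, quantize_8bit = FALSE,
                                        seed = 42L))
}

# the default (moderate-noise) study conditions
sim_noisy <- function() {
  cached_sim("noisy", simulation_config(seed = 42L))
}

# run the pipeline stages on an in-memory simulation (no file I/O, no
# alignment unless the scene was jittered)
pipeline_on_sim <- function(sim, cfg, align = FALSE) {
  stack <- extract_green(sim$rgb, cfg$frame_rate_hz, sim$truth$cycle_bounds)
  stack <- flag_and_replace_blurry(stack)
  if (align) stack <- align_stack(stack)
  cr <- crop_to_disc(stack, sim$truth$disc_mask)
  bb <- cr$bbox
  vm <- sim$truth$vein_mask[bb["rmin"]:bb["rmax"], bb["cmin"]:bb["cmax"]]
  mmpp <- calibrate_mm_per_pixel(cr$mask, sim$truth$disc_vertical_diameter_mm)
  geom <- extract_centreline(vm, disc_centroid(cr$mask), mmpp,
                             disc_mask = cr$mask)
  geom <- clip_to_disc(geom)
  fits <- fit_centreline_pixels(neg_log_transform(cr$stack), geom)
  profile <- smooth_phase(build_phase_profile(fits))
  segment <- select_segment(profile)
  est <- estimate_pwv(profile, segment, mean_cycle_time(stack))
  list(stack = cr$stack, geometry = geom, fits = fits, profile = profile,
       segment = segment, est = est)
}

# minimal centreline-fit table with prescribed first-harmonic phases, for
# profile/segment/velocity tests
fits_df <- function(phi1, d = seq_along(phi1) * 0.01 - 0.01,
                    converged = TRUE, hrwa = 1) {
  n <- length(phi1)
  data.frame(row = seq_len(n), col = 1L, distance_mm = d,
             a0 = 0, a1 = 0, b1 = 1, a2 = 0, b2 = 0, rho = 0,
             A1 = 1, phi1 = phi1, A2 = 0, phi2 = 0,
             hrwa = rep_len(hrwa, n), r2_adj = 0.9, sigma2 = 1,
             converged = rep_len(converged, n))
}

# textured frame with reproducible content, for sharpness/registration tests
texture_frame <- function(nr = 64L, nc = 64L, seed = 1L) {
  set.seed(seed)
  m <- matrix(stats::runif(nr * nc), nr, nc)
  as.matrix(stats::filter(m, rep(1 / 3, 3), circular = TRUE))
}
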