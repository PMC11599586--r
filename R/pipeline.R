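#' Read a frame sequence from disk
#'
#' Accepts a multi-frame TIFF or a directory of single-frame PNG/TIFF files
#' (lexicographic filename order = time order). RGB frames are returned as
#' a `(rows, cols, 3, time)` array, grayscale ones as
#' `(rows, cols, time)`.
#'
#' @param path TIFF file or directory.
#' @return numeric array (see above) with intensities in `[0, 1]`.
#' @export
read_frames <- function(path) {
  read1 <- function(f) {
    ext <- tolower(tools::file_ext(f))
    if (ext %in% c("tif", "tiff")) tiff::readTIFF(f, all = TRUE)
    else if (ext == "png") list(png::readPNG(f))
    else stop("input-format error: unsupported frame format '", ext, "'")
  }
  frames <- if (dir.exists(path)) {
    fs <- sort(list.files(path, pattern = "\\.(tif|tiff|png)$",
                          ignore.case = TRUE, full.names = TRUE))
    if (length(fs) == 0L) stop("input error: no frames in ", path)
    unlist(lapply(fs, read1), recursive = FALSE)
  } else {
    read1(path)
  }
  dims <- dim(frames[[1L]])
  rgb <- length(dims) == 3L && dims[3L] >= 3L
  if (rgb) {
    out <- array(0, c(dims[1L], dims[2L], 3L, length(frames)))
    for (i in seq_along(frames)) out[, , , i] <- frames[[i]][, , 1:3]
  } else {
    out <- array(0, c(dims[1L], dims[2L], length(frames)))
    for (i in seq_along(frames)) {
      f <- frames[[i]]
      out[, , i] <- if (length(dim(f)) == 3L) f[, , 1L] else f
    }
  }
  out
}

#' Read a binary ROI mask
#'
#' 8-bit PNG/TIFF; any nonzero pixel is inside the region of interest.
#'
#' @param path image file.
#' @return logical matrix.
#' @export
read_mask <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") png::readPNG(path) else tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img != 0
}

#' Write the temporal mean image for manual annotation
#'
#' The pixel-wise average of the aligned frames is the image on which the
#' optic-disc and vein masks are drawn; this writes it as PNG or TIFF for
#' the annotation round-trip.
#'
#' @param stack an aligned `frame_stack`.
#' @param out_path output `.png` or `.tif` path.
#' @return invisibly, the mean image matrix.
#' @export
annotate_average_image <- function(stack, out_path) {
  avg <- average_image(stack)
  img <- pmin(pmax(avg, 0), 1)
  ext <- tolower(tools::file_ext(out_path))
  if (ext == "png") png::writePNG(img, out_path)
  else tiff::writeTIFF(img, out_path, bits.per.sample = 16L)
  invisible(avg)
}

#' Read a pipeline run configuration
#'
#' YAML (or JSON) file with paths relative to the config file: `video`,
#' `disc_mask`, `vein_mask`; acquisition metadata `frame_rate_hz`,
#' `cycle_bounds` (list of 0-based half-open `[start, end)` frame-index
#' pairs, supplied externally from the pulse-oximeter audio) and
#' `disc_vertical_diameter_mm` (from OCT); plus optional processing
#' parameters understood by [run_pipeline()].
#'
#' @param path config file.
#' @return named list with absolute paths.
#' @export
read_run_config <- function(path) {
  cfg <- if (tolower(tools::file_ext(path)) == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  base <- dirname(normalizePath(path))
  for (f in c("video", "disc_mask", "vein_mask")) {
    if (!is.null(cfg[[f]]) && !grepl("^/", cfg[[f]])) {
      cfg[[f]] <- file.path(base, cfg[[f]])
    }
  }
  cfg$cycle_bounds <- do.call(rbind, lapply(cfg$cycle_bounds, unlist))
  cfg
}

transform_params <- function(M) {
  c(a11 = M[1L, 1L], a12 = M[1L, 2L], dr = M[1L, 3L],
    a21 = M[2L, 1L], a22 = M[2L, 2L], dc = M[2L, 3L])
}

#' Run the full PWV pipeline
#'
#' Preprocessing (green channel, sharpness QC, blur replacement, alignment,
#' disc crop), geometry (calibration, centreline, disc clipping), per-pixel
#' harmonic regression on negative-log intensities, phase profiling, loess
#' segment selection and PWV estimation, with all intermediate artefacts
#' written under `out_dir`: `qc_frames.csv`, `average_image.png`,
#' `centreline.csv`, `fits.csv`, `phase_profile.csv`, `pwv.json`,
#' `phase_profile.png` and `run.log`.
#'
#' @param config a list as returned by [read_run_config()], or a path to
#'   the config file. Recognised processing options (with defaults):
#'   `threshold_fraction` (0.75), `log_sigma` (2), `align` (TRUE),
#'   `loess_span` (0.5), `boundary_extrema` (TRUE), `seed` (1),
#'   `write_plots` (TRUE).
#' @param out_dir output directory (created if needed); overrides
#'   `config$out_dir`.
#' @return invisibly, a result bundle: list with `stack`, `geometry`,
#'   `fits`, `profile`, `segment`, `pwv`, `out_dir`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  for (f in c("video", "disc_mask", "vein_mask")) {
    if (is.null(config[[f]]) || !file.exists(config[[f]])) {
      stop("config error: missing input '", f, "'")
    }
  }
  opt <- function(name, default) {
    if (is.null(config[[name]])) default else config[[name]]
  }
  out_dir <- if (is.null(out_dir)) opt("out_dir", "veinpwv_run") else out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "run.log")
  log_line <- function(...) {
    cat(sprintf(...), "\n", sep = "", file = logf, append = TRUE)
  }
  cat("", file = logf)
  set.seed(opt("seed", 1L))
  log_line("veinpwv %s | seed %d", as.character(utils::packageVersion("veinpwv")),
           opt("seed", 1L))

  frames <- read_frames(config$video)
  stack <- if (length(dim(frames)) == 4L) {
    extract_green(frames, config$frame_rate_hz, config$cycle_bounds)
  } else {
    frame_stack(frames, config$frame_rate_hz, config$cycle_bounds)
  }
  log_line("preprocess | %d frames %dx%d, %d cycles", n_frames(stack),
           dim(stack$frames)[1L], dim(stack$frames)[2L],
           nrow(stack$cycle_bounds))

  stack <- score_sharpness(stack, sigma = opt("log_sigma", 2))
  stack <- flag_and_replace_blurry(stack, opt("threshold_fraction", 0.75))
  log_line("qc | %d blurry frame(s) replaced (threshold %.2f of max)",
           sum(!is.na(stack$qc$replaced_by)), opt("threshold_fraction", 0.75))
  if (isTRUE(opt("align", TRUE))) {
    stack <- align_stack(stack)
    log_line("align | reference frame %d", stack$reference)
  }

  disc_mask <- read_mask(config$disc_mask)
  vein_mask <- read_mask(config$vein_mask)
  cr <- crop_to_disc(stack, disc_mask)
  bb <- cr$bbox
  vein_mask <- vein_mask[bb["rmin"]:bb["rmax"], bb["cmin"]:bb["cmax"]]
  stack_c <- cr$stack

  qc <- stack$qc
  qc <- cbind(qc, do.call(rbind, lapply(stack$transforms, transform_params)))
  utils::write.csv(qc, file.path(out_dir, "qc_frames.csv"),
                   row.names = FALSE)
  annotate_average_image(stack_c, file.path(out_dir, "average_image.png"))

  mmpp <- calibrate_mm_per_pixel(cr$mask, config$disc_vertical_diameter_mm)
  centre <- disc_centroid(cr$mask)
  geom <- extract_centreline(vein_mask, centre, mmpp, disc_mask = cr$mask)
  full_geom <- geom
  geom <- clip_to_disc(geom)
  log_line("geometry | %.4g mm/px; %d/%d centreline px in disc; L_boundary %.3f mm",
           mmpp, nrow(geom$centreline), nrow(full_geom$centreline),
           geom$L_boundary_mm)
  inside <- seq_len(nrow(full_geom$centreline)) <= nrow(geom$centreline)
  utils::write.csv(data.frame(
    index = seq_len(nrow(full_geom$centreline)) - 1L,
    row = full_geom$centreline[, 1L], col = full_geom$centreline[, 2L],
    distance_mm = full_geom$distances_mm, inside_disc = inside),
    file.path(out_dir, "centreline.csv"), row.names = FALSE)

  absorb <- neg_log_transform(stack_c)
  if (absorb$n_clamped > 0L) {
    log_line("signal | %d zero-intensity pixel value(s) clamped",
             absorb$n_clamped)
  }
  fits <- fit_centreline_pixels(absorb, geom)
  utils::write.csv(fits, file.path(out_dir, "fits.csv"), row.names = FALSE)
  log_line("fit | %d/%d pixel fits converged", sum(fits$converged),
           nrow(fits))

  profile <- build_phase_profile(fits)
  profile <- smooth_phase(profile, span = opt("loess_span", 0.5))
  segment <- select_segment(profile,
                            boundary_extrema = opt("boundary_extrema", TRUE))
  pwv <- estimate_pwv(profile, segment, mean_cycle_time(stack))
  utils::write.csv(data.frame(
    distance_mm = profile$distance_mm, phase_rad = profile$phase,
    loess_phase_rad = profile$loess_phase, hrwa = profile$hrwa,
    r2_adj = profile$r2_adj),
    file.path(out_dir, "phase_profile.csv"), row.names = FALSE)
  jsonlite::write_json(unclass(pwv), file.path(out_dir, "pwv.json"),
                       auto_unbox = TRUE, digits = NA)
  if (isTRUE(opt("write_plots", TRUE))) {
    plot_phase_profile(profile, pwv,
                       file = file.path(out_dir, "phase_profile.png"))
  }
  log_line("pwv | %.2f mm/s (beta %.4f rad/mm, Ts %.3f s, segment %.3f mm, %s)",
           pwv$pwv_mm_per_s, pwv$beta, pwv$Ts_seconds, pwv$L_segment_mm,
           pwv$orientation)
  invisible(list(stack = stack_c, geometry = geom, fits = fits,
                 profile = profile, segment = segment, pwv = pwv,
                 out_dir = out_dir))
}
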