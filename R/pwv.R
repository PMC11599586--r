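#' Build the distance-phase profile along the centreline
#'
#' Takes the first-harmonic phase of each converged in-disc centreline fit,
#' unwraps it sequentially along the path (the arctangent is only defined
#' modulo 2 pi), and normalizes it to zero at the origin pixel by
#' subtracting the initial value. HRWA and adjusted R-squared ride along for
#' plotting and quality control.
#'
#' @param fits data frame from [fit_centreline_pixels()] (in path order).
#' @param max_excluded_fraction abort when more than this fraction of pixels
#'   failed to converge (default 0.2).
#' @return object of class `phase_profile`: list with `distance_mm`,
#'   `phase` (unwrapped, origin-normalized, radians), `hrwa`, `r2_adj`,
#'   `loess_phase` (NA until smoothed), `n_excluded`.
#' @export
build_phase_profile <- function(fits, max_excluded_fraction = 0.2) {
  bad <- !fits$converged
  if (any(bad)) {
    warning(sprintf("%d non-converged centreline fit(s) excluded", sum(bad)))
    if (mean(bad) > max_excluded_fraction) {
      stop("processing error: more than ",
           round(100 * max_excluded_fraction), "% of centreline fits failed")
    }
    fits <- fits[!bad, , drop = FALSE]
  }
  ph <- as.numeric(signal::unwrap(fits$phi1))
  structure(list(
    distance_mm = fits$distance_mm,
    phase = ph - ph[1L],
    hrwa = fits$hrwa,
    r2_adj = fits$r2_adj,
    loess_phase = rep(NA_real_, nrow(fits)),
    n_excluded = sum(bad)
  ), class = "phase_profile")
}

#' Loess-smooth the phase profile
#'
#' Locally weighted quadratic regression (tricube weights, neighbourhood
#' fraction `span`) of phase on distance. The smooth curve is used only to
#' locate the phase extrema that bound the analysis segment; the raw phases
#' are left untouched and are what the PWV line is fitted to.
#'
#' @param profile a `phase_profile` with at least 5 points.
#' @param span loess span (default 0.5).
#' @param degree local polynomial degree (default 2).
#' @return the profile with `loess_phase` filled in.
#' @export
smooth_phase <- function(profile, span = 0.5, degree = 2) {
  n <- length(profile$phase)
  if (n < 5L) stop("smooth_phase needs at least 5 points")
  df <- data.frame(d = profile$distance_mm, p = profile$phase)
  sm <- tryCatch(
    stats::predict(stats::loess(p ~ d, data = df, span = span,
                                degree = degree,
                                control = stats::loess.control(
                                  surface = "direct"))),
    error = function(e) NULL)
  if (is.null(sm) || anyNA(sm)) {
    warning("loess failed; falling back to a linear smooth")
    sm <- stats::fitted(stats::lm(p ~ d, data = df))
  }
  profile$loess_phase <- as.numeric(sm)
  profile
}

## Interior extrema of a discrete curve: strict sign changes of the first
## differences, plateau runs collapsed to their midpoint. Returns 1-based
## indices.
local_extrema <- function(v) {
  d <- diff(v)
  s <- sign(d)
  nz <- which(s != 0)
  if (length(nz) < 2L) return(list(max = integer(0), min = integer(0)))
  mx <- integer(0); mn <- integer(0)
  for (k in seq_len(length(nz) - 1L)) {
    i <- nz[k]; j <- nz[k + 1L]
    if (s[i] > 0 && s[j] < 0) mx <- c(mx, floor((i + 1 + j) / 2))
    if (s[i] < 0 && s[j] > 0) mn <- c(mn, floor((i + 1 + j) / 2))
  }
  list(max = mx, min = mn)
}

#' Select the analysis segment from the smoothed phase profile
#'
#' On the loess curve, finds the first local phase maximum at or after the
#' origin and the first subsequent local minimum; the closed index interval
#' between them is the segment whose raw distance-phase points the PWV line
#' is fitted to. If the curve decreases from the origin, the origin itself
#' counts as the first local maximum (boundary-extremum convention).
#'
#' A wave travelling toward the disc centre produces the mirror-image
#' profile -- rising to a turning point, then falling -- on which a
#' maximum-to-minimum rule can only latch onto noise wiggles. Orientation
#' is therefore decided first, from the global shape of the smoothed
#' curve: `"forward"` (down-then-up) when its global maximum precedes its
#' global minimum, `"reversed"` (up-then-down) otherwise. In the reversed
#' case the symmetric first minimum-to-maximum pair is selected, yielding
#' a positive slope and hence a negative (inward) velocity. A monotone
#' profile has no qualifying extrema in either orientation and raises a
#' "segment undetectable" error.
#'
#' The observation that HRWA peaks inside the selected interval is checked
#' and reported as a QC flag, not enforced.
#'
#' @param profile a `phase_profile` with `loess_phase` set.
#' @param boundary_extrema logical: apply the origin boundary-extremum
#'   convention (default TRUE).
#' @param min_points smallest admissible segment size (default 3, the
#'   least squares line's own precondition); extremum pairs spanning fewer
#'   points are degenerate and skipped.
#' @return list with `start`, `end` (1-based indices into the profile),
#'   `orientation` (`"forward"` or `"reversed"`), and
#'   `hrwa_max_inside` (QC flag).
#' @export
select_segment <- function(profile, boundary_extrema = TRUE,
                           min_points = 3L) {
  v <- profile$loess_phase
  if (anyNA(v)) stop("smooth the profile first (smooth_phase)")
  ex <- local_extrema(v)
  d1 <- diff(v)
  first_move <- d1[which(d1 != 0)[1L]]
  if (length(first_move) == 0L || is.na(first_move)) {
    stop("processing error: segment undetectable (flat profile)")
  }
  first_pair <- function(starts, ends) {
    for (m in starts) {
      after <- ends[ends >= m + min_points - 1L]
      if (length(after) > 0L) return(c(m, after[1L]))
    }
    NULL
  }
  forward <- which.max(v) < which.min(v)
  seg <- NULL
  if (forward) {
    maxima <- ex$max
    if (boundary_extrema && first_move < 0) maxima <- c(1L, maxima)
    p <- first_pair(maxima, ex$min)
    if (!is.null(p)) {
      seg <- list(start = p[1L], end = p[2L], orientation = "forward")
    }
  } else {
    minima <- ex$min
    if (boundary_extrema && first_move > 0) minima <- c(1L, minima)
    p <- first_pair(minima, ex$max)
    if (!is.null(p)) {
      seg <- list(start = p[1L], end = p[2L], orientation = "reversed")
    }
  }
  if (is.null(seg)) {
    stop("processing error: segment undetectable (monotone phase profile)")
  }
  idx <- seg$start:seg$end
  seg$hrwa_max_inside <- which.max(profile$hrwa) %in% idx
  seg
}

#' Estimate the pulse wave velocity from the distance-phase slope
#'
#' Fits an ordinary least squares line to the raw (not loess-smoothed)
#' phase versus distance within the selected closed interval and converts
#' the slope `beta` (radians/mm) to a velocity via `c = -2*pi / (beta *
#' Ts)`, where `Ts` is the mean cardiac cycle time in seconds. Distance
#' increases from the disc centre outward, so a negative slope gives a
#' positive velocity: a wave travelling toward the optic-disc boundary.
#'
#' @param profile a `phase_profile`.
#' @param segment list with `start` and `end` indices, from
#'   [select_segment()] (or constructed directly).
#' @param Ts_seconds mean cardiac cycle duration, seconds.
#' @return object of class `pwv_estimate`: list with `beta` (slope,
#'   rad/mm), `slope_stderr`, `Ts_seconds`, `pwv_mm_per_s` (signed),
#'   `speed_mm_per_s`, `segment_start_mm`, `segment_end_mm`,
#'   `L_segment_mm`, `n_points`, `max_hrwa`, and the segment QC flags.
#' @export
estimate_pwv <- function(profile, segment, Ts_seconds) {
  stopifnot(Ts_seconds > 0)
  idx <- segment$start:segment$end
  if (length(idx) < 3L) stop("segment has fewer than 3 points")
  d <- profile$distance_mm[idx]
  p <- profile$phase[idx]
  if (diff(range(d)) == 0) stop("input error: degenerate distances")
  fit <- stats::lm(p ~ d)
  beta <- unname(stats::coef(fit)[2L])
  # suppressWarnings: summary.lm warns on numerically perfect fits, for
  # which the reported standard error (~0) is exactly what we want
  se <- tryCatch(suppressWarnings(summary(fit)$coefficients[2L, 2L]),
                 error = function(e) NA_real_)
  if (abs(beta) < .Machine$double.eps) {
    stop("infinite-velocity error: zero distance-phase slope")
  }
  if (length(idx) < 10L) {
    warning("short segment (", length(idx), " points); PWV estimate will ",
            "have low signal-to-noise ratio")
  }
  structure(list(
    beta = beta,
    slope_stderr = unname(se),
    Ts_seconds = Ts_seconds,
    pwv_mm_per_s = -2 * pi / (beta * Ts_seconds),
    speed_mm_per_s = abs(-2 * pi / (beta * Ts_seconds)),
    segment_start_mm = d[1L],
    segment_end_mm = d[length(d)],
    L_segment_mm = d[length(d)] - d[1L],
    n_points = length(idx),
    max_hrwa = if (all(is.na(profile$hrwa))) NA_real_
               else max(profile$hrwa, na.rm = TRUE),
    orientation = segment$orientation,
    hrwa_max_inside = segment$hrwa_max_inside
  ), class = "pwv_estimate")
}

#' @export
print.pwv_estimate <- function(x, ...) {
  cat(sprintf("<pwv_estimate> PWV = %.2f mm/s (speed %.2f mm/s)\n",
              x$pwv_mm_per_s, x$speed_mm_per_s))
  cat(sprintf("  slope beta = %.4f rad/mm (SE %.4f), Ts = %.3f s\n",
              x$beta, x$slope_stderr, x$Ts_seconds))
  cat(sprintf("  segment [%.3f, %.3f] mm (L_segment %.3f mm, %d points)\n",
              x$segment_start_mm, x$segment_end_mm, x$L_segment_mm,
              x$n_points))
  invisible(x)
}

#' Plot the phase profile and the fitted PWV line
#'
#' Two stacked panels mirroring the method's diagnostic figure: phase of
#' the first harmonic plus HRWA against distance (with the loess curve and,
#' when supplied, the least squares line over the selected segment), and
#' adjusted R-squared against distance.
#'
#' @param profile a `phase_profile`.
#' @param estimate optional `pwv_estimate` to overlay.
#' @param file optional PNG path; when given the plot is written there.
#' @return invisibly, NULL.
#' @export
plot_phase_profile <- function(profile, estimate = NULL, file = NULL) {
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 700)
    on.exit(grDevices::dev.off())
  }
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 4))
  on.exit(graphics::par(op), add = TRUE)
  d <- profile$distance_mm
  graphics::plot(d, profile$phase, pch = 16, cex = 0.6,
                 xlab = "Distance (mm)", ylab = "Phase (rad)")
  if (!anyNA(profile$loess_phase)) {
    graphics::lines(d, profile$loess_phase, col = "red")
  }
  if (!is.null(estimate)) {
    sel <- d >= estimate$segment_start_mm & d <= estimate$segment_end_mm
    fit <- stats::lm(profile$phase[sel] ~ d[sel])
    graphics::lines(d[sel], stats::fitted(fit), col = "blue", lwd = 2)
  }
  graphics::par(new = TRUE)
  graphics::plot(d, profile$hrwa, type = "l", col = "darkgreen", axes = FALSE,
                 xlab = "", ylab = "")
  graphics::axis(4); graphics::mtext("HRWA (Au)", side = 4, line = 2.5)
  graphics::plot(d, profile$r2_adj, type = "l", xlab = "Distance (mm)",
                 ylab = "R-squared adjusted", ylim = c(0, 1))
  invisible(NULL)
}
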