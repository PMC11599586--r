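#' Frame stack container
#'
#' A `frame_stack` holds a time-ordered sequence of single-channel frames
#' together with acquisition metadata and per-frame quality-control state.
#' Frames are stored as a numeric array with dimensions
#' `(rows, cols, time)`; pixel coordinates throughout the package are
#' 0-based `(row, col)` with the row index increasing downward.
#'
#' @param frames numeric array of dimension `(rows, cols, n_frames)` with
#'   non-negative intensities. A matrix is promoted to a single-frame stack.
#' @param frame_rate_hz positive scalar, frames per second.
#' @param cycle_bounds integer matrix with columns `start`, `end`: one row
#'   per cardiac cycle, 0-based half-open frame-index intervals `[start, end)`
#'   in temporal order, non-overlapping and contiguous.
#'
#' @return An object of class `frame_stack`: a list with elements `frames`,
#'   `frame_rate_hz`, `cycle_bounds`, and a per-frame data frame `qc` with
#'   columns `frame` (0-based index), `sharpness` (NA until computed),
#'   `replaced_by` (NA or 0-based donor index) plus a list `transforms` of
#'   3x3 homogeneous matrices acting on `(row, col, 1)` coordinates
#'   (identity until alignment).
#' @export
frame_stack <- function(frames, frame_rate_hz, cycle_bounds = NULL) {
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1L))
  stopifnot(is.array(frames), length(dim(frames)) == 3L)
  if (any(frames < 0)) stop("frame intensities must be non-negative")
  if (!is.numeric(frame_rate_hz) || length(frame_rate_hz) != 1L ||
      frame_rate_hz <= 0) {
    stop("frame_rate_hz must be a positive scalar")
  }
  n <- dim(frames)[3L]
  if (!is.null(cycle_bounds)) {
    cycle_bounds <- validate_cycle_bounds(cycle_bounds, n)
  }
  qc <- data.frame(frame = seq_len(n) - 1L, sharpness = NA_real_,
                   replaced_by = NA_integer_)
  structure(list(
    frames = frames,
    frame_rate_hz = frame_rate_hz,
    cycle_bounds = cycle_bounds,
    qc = qc,
    transforms = rep(list(diag(3)), n),
    reference = NA_integer_
  ), class = "frame_stack")
}

validate_cycle_bounds <- function(cycle_bounds, n_frames) {
  cb <- as.matrix(cycle_bounds)
  if (ncol(cb) != 2L) stop("cycle_bounds must have two columns [start, end)")
  storage.mode(cb) <- "integer"
  colnames(cb) <- c("start", "end")
  if (any(cb[, 1L] >= cb[, 2L])) stop("empty cycle in cycle_bounds")
  if (any(cb < 0L) || any(cb[, 2L] > n_frames)) {
    stop("cycle_bounds outside the frame range")
  }
  if (nrow(cb) > 1L && any(cb[-1L, 1L] != cb[-nrow(cb), 2L])) {
    stop("cycle_bounds must be contiguous and in temporal order")
  }
  cb
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_stack> %d frames of %d x %d @ %.3g fps\n",
              d[3L], d[1L], d[2L], x$frame_rate_hz))
  if (!is.null(x$cycle_bounds)) {
    cat(sprintf("  %d cardiac cycle(s): %s\n", nrow(x$cycle_bounds),
                paste(sprintf("[%d,%d)", x$cycle_bounds[, 1L],
                              x$cycle_bounds[, 2L]), collapse = " ")))
  }
  nrep <- sum(!is.na(x$qc$replaced_by))
  if (nrep > 0L) cat(sprintf("  %d frame(s) replaced as blurry\n", nrep))
  if (!is.na(x$reference)) cat(sprintf("  reference frame: %d\n", x$reference))
  invisible(x)
}

n_frames <- function(stack) dim(stack$frames)[3L]

#' Mean cardiac cycle duration of a stack, in seconds
#'
#' Average of the recorded cycle durations implied by `cycle_bounds` and the
#' frame rate.
#'
#' @param stack a `frame_stack` with cycle bounds set.
#' @return positive scalar, seconds per cycle.
#' @export
mean_cycle_time <- function(stack) {
  if (is.null(stack$cycle_bounds)) stop("stack has no cycle_bounds")
  mean(stack$cycle_bounds[, 2L] - stack$cycle_bounds[, 1L]) /
    stack$frame_rate_hz
}
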