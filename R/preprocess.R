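#' Extract the green channel from an RGB frame sequence
#'
#' The green channel is used because a haemoglobin absorption peak coincides
#' with an isosbestic point of oxy- and deoxyhaemoglobin near 550 nm, making
#' green intensity a robust proxy for blood column thickness regardless of
#' oxygen saturation.
#'
#' @param rgb_frames numeric array `(rows, cols, 3, n_frames)` of
#'   non-negative intensities, channel order R, G, B.
#' @param frame_rate_hz frames per second.
#' @param cycle_bounds cardiac-cycle frame intervals; see [frame_stack()].
#' @return a [frame_stack()] whose frames are the unmodified green channel.
#' @export
extract_green <- function(rgb_frames, frame_rate_hz, cycle_bounds = NULL) {
  if (!is.array(rgb_frames) || length(dim(rgb_frames)) != 4L) {
    stop("input-format error: expected a (rows, cols, channel, time) array")
  }
  if (dim(rgb_frames)[3L] != 3L) {
    stop("input-format error: expected exactly 3 colour channels")
  }
  if (any(rgb_frames < 0)) stop("input-format error: negative intensities")
  g <- rgb_frames[, , 2L, , drop = FALSE]
  g <- array(g, dim(rgb_frames)[c(1L, 2L, 4L)])
  frame_stack(g, frame_rate_hz, cycle_bounds)
}

#' Laplacian-of-Gaussian kernel
#'
#' Discrete LoG kernel, normalised to zero sum so that constant image
#' regions map exactly to zero.
#'
#' @param sigma Gaussian scale in pixels.
#' @return square numeric matrix of side `2 * ceiling(3 * sigma) + 1`.
#' @export
log_kernel <- function(sigma = 2) {
  stopifnot(sigma > 0)
  h <- ceiling(3 * sigma)
  x <- seq(-h, h)
  g <- outer(x, x, function(r, c) {
    s2 <- sigma^2
    r2 <- r^2 + c^2
    (r2 - 2 * s2) / s2^2 * exp(-r2 / (2 * s2))
  })
  g - mean(g)
}

#' Frame sharpness score
#'
#' Applies a Laplacian-of-Gaussian filter (which responds to edges) and
#' returns the standard deviation of the filtered frame. Blurring attenuates
#' high-frequency edge content, so blurrier frames score lower. The score is
#' invariant to adding a constant to the frame.
#'
#' @param frame 2-D numeric matrix.
#' @param sigma LoG scale in pixels (default 2, the vessel-edge scale of a
#'   200-300 pixel optic-disc crop).
#' @return non-negative scalar.
#' @export
sharpness_score <- function(frame, sigma = 2) {
  stopifnot(is.matrix(frame), length(frame) > 0L)
  f <- EBImage::filter2(frame, log_kernel(sigma), boundary = "replicate")
  stats::sd(as.numeric(f))
}

#' Score sharpness of every frame in a stack
#'
#' @inheritParams sharpness_score
#' @param stack a `frame_stack`.
#' @return the stack with `qc$sharpness` filled in.
#' @export
score_sharpness <- function(stack, sigma = 2) {
  k <- log_kernel(sigma)
  stack$qc$sharpness <- vapply(seq_len(n_frames(stack)), function(i) {
    stats::sd(as.numeric(EBImage::filter2(stack$frames[, , i], k,
                                          boundary = "replicate")))
  }, numeric(1))
  stack
}

#' Flag blurry frames and replace them with the nearest sharp frame
#'
#' A frame is blurry when its sharpness score falls below
#' `threshold_fraction` of the sharpest frame's score. Each blurry frame's
#' pixel data is replaced by the temporally nearest non-blurry frame
#' (earlier frame wins ties); the substitution is recorded in
#' `qc$replaced_by`. The number of frames and the cycle partition are
#' unchanged.
#'
#' @param stack a `frame_stack`; sharpness is computed first if absent.
#' @param threshold_fraction blur threshold as a fraction of the maximum
#'   sharpness (default 0.75).
#' @param sigma LoG scale used if sharpness must be computed.
#' @return the stack with blurry frames substituted and bookkeeping set.
#' @export
flag_and_replace_blurry <- function(stack, threshold_fraction = 0.75,
                                    sigma = 2) {
  if (anyNA(stack$qc$sharpness)) stack <- score_sharpness(stack, sigma)
  s <- stack$qc$sharpness
  thr <- threshold_fraction * max(s)
  blurry <- which(s < thr)
  good <- which(s >= thr)
  if (length(good) == 0L) stop("processing error: all frames are blurry")
  for (i in blurry) {
    d <- abs(good - i)
    donor <- good[which.min(d)]          # which.min: earliest wins ties
    stack$frames[, , i] <- stack$frames[, , donor]
    stack$qc$replaced_by[i] <- donor - 1L
  }
  stack
}

#' Crop a stack (and mask) to the bounding box of a binary mask
#'
#' After alignment the stack is cropped to the tight bounding box of the
#' optic-disc mask (typically around 200 x 300 pixels), which bounds the
#' per-pixel fitting work to the region of interest.
#'
#' @param stack a `frame_stack`.
#' @param disc_mask logical/0-1 matrix, same shape as the frames.
#' @return list with elements `stack` (cropped frames) and `mask` (cropped
#'   mask), plus `bbox` (`rmin`, `rmax`, `cmin`, `cmax`, 1-based inclusive).
#' @export
crop_to_disc <- function(stack, disc_mask) {
  d <- dim(stack$frames)
  if (!all(dim(disc_mask) == d[1:2])) {
    stop("input error: mask shape differs from frame shape")
  }
  idx <- which(disc_mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("input error: empty mask")
  rr <- range(idx[, 1L]); cc <- range(idx[, 2L])
  stack$frames <- stack$frames[rr[1L]:rr[2L], cc[1L]:cc[2L], , drop = FALSE]
  list(stack = stack,
       mask = disc_mask[rr[1L]:rr[2L], cc[1L]:cc[2L]] != 0,
       bbox = c(rmin = rr[1L], rmax = rr[2L], cmin = cc[1L], cmax = cc[2L]))
}

#' Temporal mean image of a stack
#'
#' The pixel-wise intensity average of all frames of the aligned stack; the
#' image on which the optic-disc and vein regions of interest are drawn.
#'
#' @param stack a `frame_stack` with at least one frame.
#' @return numeric matrix.
#' @export
average_image <- function(stack) {
  if (n_frames(stack) == 0L) stop("input error: empty stack")
  rowMeans(stack$frames, dims = 2L)
}
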