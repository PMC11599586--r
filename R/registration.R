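## Multi-stage intensity-based registration: translation (FFT phase
## correlation, subpixel) -> rigid -> affine (direct optimisation of masked
## SSD). The contract is transform recovery, not a particular detector.

#' Warp an image by a backward affine map
#'
#' `output[p] = img[M %*% c(p, 1)]` with bilinear interpolation; `p` is a
#' 0-based `(row, col)` pixel coordinate. Source coordinates outside the
#' image are clamped to the edge (edge replication), so warping never
#' introduces zeros that would corrupt a later negative-log transform.
#'
#' @param img numeric matrix.
#' @param M 3x3 homogeneous matrix mapping output `(row, col, 1)` to source
#'   coordinates (a backward map).
#' @return numeric matrix, same shape as `img`.
#' @export
warp_affine <- function(img, M) {
  d <- dim(img)
  rc <- as.matrix(expand.grid(r = seq_len(d[1L]) - 1, c = seq_len(d[2L]) - 1))
  matrix(warp_values(img, M, rc), d[1L], d[2L])
}

## Bilinear sample of img at M %*% (rc, 1), edge-clamped; rc is an n x 2
## matrix of 0-based (row, col) output coordinates.
warp_values <- function(img, M, rc) {
  d <- dim(img)
  src <- cbind(rc, 1) %*% t(M[1:2, , drop = FALSE])
  sr <- pmin(pmax(src[, 1L], 0), d[1L] - 1)
  sc <- pmin(pmax(src[, 2L], 0), d[2L] - 1)
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0;   fc <- sc - c0
  r1 <- pmin(r0 + 1, d[1L] - 1); c1 <- pmin(c0 + 1, d[2L] - 1)
  img[cbind(r0 + 1, c0 + 1)] * (1 - fr) * (1 - fc) +
    img[cbind(r1 + 1, c0 + 1)] * fr       * (1 - fc) +
    img[cbind(r0 + 1, c1 + 1)] * (1 - fr) * fc +
    img[cbind(r1 + 1, c1 + 1)] * fr       * fc
}

#' Build homogeneous transforms
#'
#' Helpers constructing 3x3 backward maps on 0-based `(row, col, 1)`
#' coordinates: a pure translation, and a rigid rotation by `theta_deg`
#' about `centre` composed with a translation.
#'
#' @param dr,dc translation in pixels (row, col).
#' @param theta_deg rotation angle, degrees, anticlockwise in (row, col)
#'   space.
#' @param centre rotation centre, 0-based (row, col).
#' @return 3x3 numeric matrix.
#' @export
affine_translation <- function(dr, dc) {
  rbind(c(1, 0, dr), c(0, 1, dc), c(0, 0, 1))
}

#' @rdname affine_translation
#' @export
affine_rigid <- function(theta_deg, dr, dc, centre) {
  th <- theta_deg * pi / 180
  R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  t0 <- centre - R %*% centre
  rbind(cbind(R, t0 + c(dr, dc)), c(0, 0, 1))
}

#' Estimate a translation between two frames by phase correlation
#'
#' Returns `(dr, dc)` such that `warp_affine(moving,
#' affine_translation(dr, dc))` best matches `reference`, with subpixel
#' refinement by parabolic interpolation of the correlation peak.
#'
#' @param reference,moving numeric matrices of equal shape.
#' @return length-2 numeric vector `(dr, dc)` with attribute `peak`, the
#'   normalised correlation-peak height (a match-confidence score).
#' @export
estimate_translation <- function(reference, moving) {
  stopifnot(all(dim(reference) == dim(moving)))
  d <- dim(reference)
  w <- outer(hann(d[1L]), hann(d[2L]))
  Fr <- stats::fft(reference * w)
  Fm <- stats::fft(moving * w)
  X <- Fr * Conj(Fm)
  X <- X / pmax(Mod(X), 1e-12)
  r <- Re(stats::fft(X, inverse = TRUE)) / length(X)
  pk <- which(r == max(r), arr.ind = TRUE)[1L, ]
  sub <- function(i, n, axis_vals) {
    # parabolic subpixel offset from the 3 wrapped samples around the peak
    y0 <- axis_vals[((i - 2) %% n) + 1L]
    y1 <- axis_vals[i]
    y2 <- axis_vals[(i %% n) + 1L]
    den <- y0 - 2 * y1 + y2
    if (abs(den) < 1e-12) 0 else 0.5 * (y0 - y2) / den
  }
  dr <- (pk[1L] - 1) + sub(pk[1L], d[1L], r[, pk[2L]])
  dc <- (pk[2L] - 1) + sub(pk[2L], d[2L], r[pk[1L], ])
  if (dr > d[1L] / 2) dr <- dr - d[1L]
  if (dc > d[2L] / 2) dc <- dc - d[2L]
  structure(c(-dr, -dc), peak = max(r))
}

hann <- function(n) {
  if (n == 1L) return(1)
  0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
}

#' Refine a registration transform by direct intensity optimisation
#'
#' Minimises the mean squared intensity difference between the reference and
#' the warped moving frame (borders of width `trim` excluded) over a rigid
#' (rotation about the image centre plus translation) or full affine
#' parameterisation, by Nelder-Mead, starting from `init`. If the refined
#' transform does not improve on `init`, `init` is returned unchanged with a
#' warning -- the fall-back behaviour for frames with too little common
#' structure.
#'
#' @param reference,moving numeric matrices of equal shape.
#' @param init 3x3 starting transform (e.g. from [estimate_translation()]).
#' @param kind `"rigid"` or `"affine"`.
#' @param trim border width (pixels) excluded from the objective.
#' @return 3x3 transform matrix.
#' @export
refine_transform <- function(reference, moving, init,
                             kind = c("rigid", "affine"), trim = 8L,
                             stride = 2L) {
  kind <- match.arg(kind)
  d <- dim(reference)
  centre <- (d - 1) / 2
  # strided in-trim grid: the objective needs relative, not absolute, SSD
  rc <- as.matrix(expand.grid(
    r = seq(trim, d[1L] - 1 - trim, by = stride),
    c = seq(trim, d[2L] - 1 - trim, by = stride)))
  refv <- reference[rc + 1L]
  obj_M <- function(M) mean((refv - warp_values(moving, M, rc))^2)
  obj_rigid <- function(p) {
    obj_M(affine_rigid(p[1L], p[2L], p[3L], centre))
  }
  obj_affine <- function(p) {
    obj_M(rbind(matrix(p, 2, 3, byrow = TRUE), c(0, 0, 1)))
  }
  if (kind == "rigid") {
    p0 <- c(0, init[1L, 3L], init[2L, 3L])
    fit <- stats::optim(p0, obj_rigid, method = "Nelder-Mead",
                        control = list(maxit = 400, reltol = 1e-12,
                                       parscale = c(0.5, 1, 1)))
    M <- affine_rigid(fit$par[1L], fit$par[2L], fit$par[3L], centre)
  } else {
    p0 <- as.numeric(t(init[1:2, ]))
    fit <- stats::optim(p0, obj_affine, method = "Nelder-Mead",
                        control = list(maxit = 600, reltol = 1e-12,
                                       parscale = c(0.01, 0.01, 1,
                                                    0.01, 0.01, 1)))
    M <- rbind(matrix(fit$par, 2, 3, byrow = TRUE), c(0, 0, 1))
  }
  if (fit$value > obj_M(init)) {
    warning(sprintf("%s refinement did not improve the fit; keeping the ",
                    kind), "previous stage's transform")
    return(init)
  }
  M
}

#' Align all frames of a stack to the sharpest frame
#'
#' Sequential registration of every frame to the reference (sharpest) frame:
#' translation first (phase correlation), then rigid, then affine
#' refinement. Each frame is warped into the reference coordinates with
#' bilinear interpolation and edge replication; the composed transform is
#' stored per frame, identity for the reference.
#'
#' @param stack a `frame_stack` with at least 2 frames.
#' @param reference `"sharpest"` (default) or a 0-based frame index.
#' @param stages character vector, a prefix of
#'   `c("translation", "rigid", "affine")`.
#' @param trim border width excluded from the refinement objective.
#' @param sigma LoG scale used if sharpness must be computed.
#' @return the stack with frames warped, `transforms` set and `reference`
#'   recorded.
#' @export
align_stack <- function(stack, reference = "sharpest",
                        stages = c("translation", "rigid", "affine"),
                        trim = 8L, sigma = 2) {
  if (n_frames(stack) < 2L) stop("align_stack needs at least 2 frames")
  stopifnot(all(stages %in% c("translation", "rigid", "affine")))
  if (identical(reference, "sharpest")) {
    if (anyNA(stack$qc$sharpness)) stack <- score_sharpness(stack, sigma)
    ref <- which.max(stack$qc$sharpness)
  } else {
    ref <- as.integer(reference) + 1L
  }
  refimg <- stack$frames[, , ref]
  for (i in seq_len(n_frames(stack))) {
    if (i == ref) {
      stack$transforms[[i]] <- diag(3)
      next
    }
    mov <- stack$frames[, , i]
    tr <- estimate_translation(refimg, mov)
    M <- affine_translation(tr[1L], tr[2L])
    if ("rigid" %in% stages) {
      M <- refine_transform(refimg, mov, M, "rigid", trim)
    }
    if ("affine" %in% stages) {
      M <- refine_transform(refimg, mov, M, "affine", trim)
    }
    stack$frames[, , i] <- warp_affine(mov, M)
    stack$transforms[[i]] <- M
  }
  stack$reference <- ref - 1L
  stack
}
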