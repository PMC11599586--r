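## Per-pixel harmonic regression on negative-log intensities:
##   y(t) = f_p(t) + f_np(t) + e_t
## f_p  = order-2 Fourier series in cardiac-cycle-fraction time t,
## f_np = continuous linear spline with knots at every cycle boundary,
## e_t  = AR(1) errors; fitted by GLS maximising the restricted likelihood.

#' Cycle-fraction time axis of a stack
#'
#' Frame `i` inside cycle `k` with bounds `[s, e)` receives
#' `t = k + (i - s) / (e - s)`: time accumulates one unit per cardiac
#' cycle, so the Fourier basis is frequency-locked to the pulse even when
#' cycle durations differ.
#'
#' @param stack a `frame_stack` with `cycle_bounds`.
#' @return list with `t` (cycle-fraction time per used frame), `frames`
#'   (0-based indices of the frames inside the cycle partition), and
#'   `cycle` (0-based cycle index per used frame).
#' @export
cycle_fraction_time <- function(stack) {
  cb <- stack$cycle_bounds
  if (is.null(cb)) stop("stack has no cycle_bounds")
  t <- numeric(0); fr <- integer(0); cy <- integer(0)
  for (k in seq_len(nrow(cb))) {
    s <- cb[k, 1L]; e <- cb[k, 2L]
    i <- s:(e - 1L)
    t <- c(t, (k - 1L) + (i - s) / (e - s))
    fr <- c(fr, i)
    cy <- c(cy, rep(k - 1L, length(i)))
  }
  list(t = t, frames = fr, cycle = cy)
}

#' Negative-log (Beer-Lambert) intensity transform
#'
#' By the Beer-Lambert law transmitted intensity decays exponentially with
#' the absorber column thickness, so `-ln(intensity)` is linearly related to
#' the axial blood-column thickness and hence to vessel diameter variation.
#' Zero intensities are clamped to one count before the logarithm (8-bit
#' convention) and the number of clamped pixels is reported.
#'
#' @param stack a `frame_stack` with cycle bounds.
#' @param clamp smallest admissible intensity. Default: `1/255` when the
#'   data look unit-scaled (max <= 1), otherwise 1.
#' @return object of class `absorbance_stack`: list with `values` (array
#'   `(rows, cols, n_used_frames)` of negative-log intensities, arbitrary
#'   units), `t` (cycle-fraction time), `frames` (0-based source frame
#'   indices), `cycle_bounds`, `frame_rate_hz`, `n_clamped`.
#' @export
neg_log_transform <- function(stack, clamp = NULL) {
  ct <- cycle_fraction_time(stack)
  v <- stack$frames[, , ct$frames + 1L, drop = FALSE]
  if (is.null(clamp)) clamp <- if (max(v) <= 1) 1 / 255 else 1
  n_clamped <- sum(v < clamp)
  v <- pmax(v, clamp)
  if (any(v <= 0)) stop("input error: non-positive intensity after clamping")
  structure(list(
    values = -log(v),
    t = ct$t,
    frames = ct$frames,
    cycle_bounds = stack$cycle_bounds,
    frame_rate_hz = stack$frame_rate_hz,
    n_clamped = n_clamped
  ), class = "absorbance_stack")
}

#' Harmonic-plus-spline design matrix
#'
#' Columns: intercept; `cos(2*pi*t)`, `sin(2*pi*t)`, `cos(4*pi*t)`,
#' `sin(4*pi*t)` (order-2 Fourier basis); and a continuous piecewise-linear
#' (truncated-power) basis with knots at every cardiac-cycle boundary for
#' the non-periodic component. Redundant truncated-power columns (those
#' that would make the matrix rank deficient, e.g. the hinge at the final
#' knot when no sample lies beyond it) are dropped so the matrix has full
#' column rank.
#'
#' @param t cycle-fraction time (accumulating across cycles).
#' @param knots cycle-boundary knot positions; default `0:K` where `K` is
#'   the number of cycles spanned by `t`.
#' @return numeric matrix with named columns and attribute `fourier_cols`.
#' @export
harmonic_design_matrix <- function(t, knots = NULL) {
  if (is.null(knots)) knots <- 0:ceiling(max(t) - 1e-9)
  if (length(knots) < 4L) {
    stop("fitting error: need at least 3 cardiac cycles")
  }
  X <- cbind(`(Intercept)` = 1,
             cos1 = cos(2 * pi * t), sin1 = sin(2 * pi * t),
             cos2 = cos(4 * pi * t), sin2 = sin(4 * pi * t))
  S <- vapply(knots[-length(knots)], function(k) pmax(t - k, 0),
              numeric(length(t)))
  colnames(S) <- paste0("sp", seq_len(ncol(S)) - 1L)
  X <- cbind(X, S)
  q <- qr(X)
  if (q$rank < ncol(X)) {
    keep <- sort(q$pivot[seq_len(q$rank)])
    if (!all(1:5 %in% keep)) {
      stop("fitting error: rank-deficient design (too few samples per cycle)")
    }
    X <- X[, keep, drop = FALSE]
  }
  attr(X, "fourier_cols") <- c("cos1", "sin1", "cos2", "sin2")
  X
}

ar1_whiten <- function(z, rho) {
  n <- NROW(z)
  if (is.matrix(z)) {
    rbind(sqrt(1 - rho^2) * z[1L, , drop = FALSE],
          z[-1L, , drop = FALSE] - rho * z[-n, , drop = FALSE])
  } else {
    c(sqrt(1 - rho^2) * z[1L], z[-1L] - rho * z[-n])
  }
}

#' Fit the harmonic regression model by GLS with AR(1) errors (REML)
#'
#' The restricted log-likelihood is profiled over the AR(1) coefficient
#' `rho`: for each candidate `rho` the model is whitened with the
#' closed-form AR(1) Cholesky transform and solved by least squares; the
#' scalar profile is maximised by bounded search. Adjusted R-squared is
#' computed on the whitened fit.
#'
#' @param y numeric vector of negative-log intensities.
#' @param t cycle-fraction time, same length as `y`.
#' @param knots cycle-boundary knots; see [harmonic_design_matrix()].
#' @param rho `NULL` to estimate (default), or a fixed value in (-1, 1)
#'   (`rho = 0` reproduces ordinary least squares exactly).
#' @param rho_bounds search interval for `rho`.
#' @param tol convergence tolerance of the scalar optimiser.
#' @return object of class `harmonic_fit`: list with `a0`, `a1`, `b1`,
#'   `a2`, `b2`, `spline_coeffs`, `rho`, `sigma2`, `r2_adj`,
#'   `A1`, `phi1`, `A2`, `phi2`, `hrwa`, `n`, `p`, `converged`,
#'   `coefficients` (full named vector), `logLik_reml` (up to a constant).
#' @export
fit_harmonic_gls <- function(y, t, knots = NULL, rho = NULL,
                             rho_bounds = c(-0.99, 0.99), tol = 1e-6) {
  stopifnot(length(y) == length(t), all(is.finite(y)))
  X <- harmonic_design_matrix(t, knots)
  n <- length(y); p <- ncol(X)
  if (n <= p + 1L) stop("fitting error: too few samples")
  reml <- function(r) {
    Wy <- ar1_whiten(y, r); WX <- ar1_whiten(X, r)
    q <- qr(WX)
    if (q$rank < p) return(list(ll = -Inf))
    co <- qr.coef(q, Wy)
    res <- Wy - WX %*% co
    rss <- sum(res^2)
    # REML profile in whitened quantities: with W'W = (1-r^2) V^{-1} the
    # |V| and |X'V^{-1}X| terms collapse to -log(1-r^2) + log|X'W'WX|.
    logdetXtWWX <- 2 * sum(log(abs(diag(qr.R(q)))))
    ll <- -0.5 * ((n - p) * log(rss) - log(1 - r^2) + logdetXtWWX)
    list(ll = ll, co = co, rss = rss, Wy = Wy, WX = WX)
  }
  if (is.null(rho)) {
    opt <- stats::optimize(function(r) reml(r)$ll, interval = rho_bounds,
                           maximum = TRUE, tol = tol)
    rho_hat <- opt$maximum
    fit <- reml(rho_hat)
  } else {
    stopifnot(abs(rho) < 1)
    rho_hat <- rho
    fit <- reml(rho_hat)
  }
  if (!is.finite(fit$ll)) stop("fitting error: singular whitened design")
  co <- fit$co
  sigma2 <- fit$rss / (n - p)
  tss <- sum((fit$Wy - mean(fit$Wy))^2)
  r2 <- 1 - fit$rss / tss
  r2_adj <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  sp <- co[grep("^sp", names(co))]
  out <- structure(list(
    a0 = unname(co["(Intercept)"]),
    a1 = unname(co["cos1"]), b1 = unname(co["sin1"]),
    a2 = unname(co["cos2"]), b2 = unname(co["sin2"]),
    spline_coeffs = sp,
    rho = rho_hat, sigma2 = sigma2, r2_adj = r2_adj,
    n = n, p = p, converged = TRUE,
    coefficients = co, logLik_reml = fit$ll
  ), class = "harmonic_fit")
  out <- to_amplitude_phase(out)
  out$hrwa <- hrwa(out)
  out
}

#' Convert Fourier coefficients to amplitude-phase form
#'
#' The periodic component `a0 + sum_n a_n cos(2 pi n t) + b_n sin(2 pi n t)`
#' is rewritten as `a0 + sum_n A_n sin(2 pi n t + phi_n)` with
#' `A_n = sqrt(a_n^2 + b_n^2)` and `phi_n = atan2(a_n, b_n)`. This
#' two-argument arctangent convention is the one for which the sine-form
#' reconstruction is an exact identity; any fixed consistent convention
#' yields the same phase differences along the vessel, which is all the PWV
#' depends on. A harmonic with `a_n = b_n = 0` gets amplitude 0, phase 0,
#' and is flagged degenerate.
#'
#' @param fit a `harmonic_fit` (or any list with `a1`, `b1`, `a2`, `b2`).
#' @return the fit with `A1`, `phi1`, `A2`, `phi2` and `degenerate` set.
#' @export
to_amplitude_phase <- function(fit) {
  conv <- function(a, b) {
    if (a == 0 && b == 0) c(0, 0, TRUE) else c(sqrt(a^2 + b^2),
                                               atan2(a, b), FALSE)
  }
  h1 <- conv(fit$a1, fit$b1); h2 <- conv(fit$a2, fit$b2)
  fit$A1 <- h1[1L]; fit$phi1 <- h1[2L]
  fit$A2 <- h2[1L]; fit$phi2 <- h2[2L]
  fit$degenerate <- c(h1 = h1[3L] > 0, h2 = h2[3L] > 0)
  fit
}

#' Evaluate the fitted periodic component
#'
#' `eval_periodic` uses the sine-cosine form; `eval_amplitude_phase` the
#' amplitude-phase form. The two agree pointwise (reconstruction identity).
#'
#' @param fit a `harmonic_fit`.
#' @param t cycle-fraction times.
#' @return numeric vector.
#' @export
eval_periodic <- function(fit, t) {
  fit$a0 + fit$a1 * cos(2 * pi * t) + fit$b1 * sin(2 * pi * t) +
    fit$a2 * cos(4 * pi * t) + fit$b2 * sin(4 * pi * t)
}

#' @rdname eval_periodic
#' @export
eval_amplitude_phase <- function(fit, t) {
  fit$a0 + fit$A1 * sin(2 * pi * t + fit$phi1) +
    fit$A2 * sin(4 * pi * t + fit$phi2)
}

#' Harmonic regression wave amplitude (HRWA)
#'
#' Peak-to-trough difference of the fitted periodic component over one
#' cardiac cycle: the maximum minus the minimum of `f_p(t)` on `[0, 1)`,
#' located on a dense grid and refined by local optimisation. HRWA is
#' invariant to the intercept and the non-periodic component.
#'
#' @param fit a `harmonic_fit` (with Fourier coefficients set).
#' @param n_grid grid resolution (default 1024).
#' @return non-negative scalar.
#' @export
hrwa <- function(fit, n_grid = 1024L) {
  tt <- seq(0, 1, length.out = n_grid + 1L)[-(n_grid + 1L)]
  v <- eval_periodic(fit, tt)
  refine <- function(i, maximum) {
    lo <- tt[i] - 1.5 / n_grid; hi <- tt[i] + 1.5 / n_grid
    stats::optimize(function(x) eval_periodic(fit, x), c(lo, hi),
                    maximum = maximum, tol = 1e-8)
  }
  mx <- refine(which.max(v), TRUE)
  mn <- refine(which.min(v), FALSE)
  unname(mx$objective - mn$objective)
}

#' @export
print.harmonic_fit <- function(x, ...) {
  cat(sprintf(paste0("<harmonic_fit> A1=%.4g phi1=%.4g  A2=%.4g phi2=%.4g",
                     "  HRWA=%.4g\n"),
              x$A1, x$phi1, x$A2, x$phi2, x$hrwa))
  cat(sprintf("  rho=%.3f sigma2=%.4g R2adj=%.4f (n=%d, p=%d)\n",
              x$rho, x$sigma2, x$r2_adj, x$n, x$p))
  invisible(x)
}

#' Fit the harmonic model at every in-disc centreline pixel
#'
#' @param absorbance an `absorbance_stack` from [neg_log_transform()].
#' @param geometry a (clipped) `vessel_geometry` whose centreline
#'   coordinates index into the absorbance frames.
#' @param ... passed to [fit_harmonic_gls()].
#' @return data frame with one row per centreline pixel: `row`, `col`,
#'   `distance_mm`, Fourier and AR(1) estimates, `A1`, `phi1`, `A2`,
#'   `phi2`, `hrwa`, `r2_adj`, `sigma2`, `converged`.
#' @export
fit_centreline_pixels <- function(absorbance, geometry, ...) {
  cl <- geometry$centreline
  res <- vector("list", nrow(cl))
  for (i in seq_len(nrow(cl))) {
    y <- absorbance$values[cl[i, 1L] + 1L, cl[i, 2L] + 1L, ]
    f <- tryCatch(fit_harmonic_gls(y, absorbance$t, ...),
                  error = function(e) NULL)
    res[[i]] <- if (is.null(f)) {
      data.frame(row = cl[i, 1L], col = cl[i, 2L],
                 distance_mm = geometry$distances_mm[i],
                 a0 = NA_real_, a1 = NA_real_, b1 = NA_real_,
                 a2 = NA_real_, b2 = NA_real_, rho = NA_real_,
                 A1 = NA_real_, phi1 = NA_real_, A2 = NA_real_,
                 phi2 = NA_real_, hrwa = NA_real_, r2_adj = NA_real_,
                 sigma2 = NA_real_, converged = FALSE)
    } else {
      data.frame(row = cl[i, 1L], col = cl[i, 2L],
                 distance_mm = geometry$distances_mm[i],
                 a0 = f$a0, a1 = f$a1, b1 = f$b1, a2 = f$a2, b2 = f$b2,
                 rho = f$rho, A1 = f$A1, phi1 = f$phi1, A2 = f$A2,
                 phi2 = f$phi2, hrwa = f$hrwa, r2_adj = f$r2_adj,
                 sigma2 = f$sigma2, converged = TRUE)
    }
  }
  do.call(rbind, res)
}
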