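---
title: "Estimating venous pulse wave velocity from PPG video: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating venous pulse wave velocity from PPG video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(veinpwv)
```

## The measurement problem

Retinal veins near the optic disc pulse visibly with the cardiac cycle.
The pulsation is a travelling wave along the vessel wall, and its speed —
the vessel pulse wave velocity (PWV) — is of interest as a window on
venous wall mechanics. Direct measurement is infeasible; instead, this
package estimates PWV from the *time displacement* of the pulse observed
at many points along the vessel in ordinary video (about 25 fps, three or
more cardiac cycles, cycle boundaries supplied externally from a
pulse-oximeter track).

Two physical facts make this work. First, by the Beer–Lambert law the
green-channel intensity at a vessel pixel decays exponentially with the
axial blood-column thickness, so `-ln(intensity)` varies linearly with
the local vessel diameter; green is used because haemoglobin absorption
there is insensitive to oxygen saturation. Second, a travelling wave of
speed `c` and period `Ts` delays the pulse at a point `x` mm along the
vessel by `x / c` seconds, i.e. shifts the phase of its fundamental
frequency by `-2*pi*x / (c*Ts)` radians. The first-harmonic phase as a
function of distance is therefore a line of slope `beta = -2*pi/(c*Ts)`,
inverted as `c = -2*pi/(beta*Ts)`. This identity is exact and is enforced
to 1e-12 by the test suite.

## The per-pixel model

Each pixel's negative-log intensity series is modelled as

* a periodic component: order-2 Fourier series in cycle-fraction time
  (the fundamental plus one overtone capture the asymmetric pulse shape
  without overfitting ~20 samples per cycle);
* a non-periodic component: continuous linear spline with knots at every
  cycle boundary, absorbing slow drift from residual motion and
  illumination;
* AR(1) errors: consecutive frames share noise (registration residues,
  sensor flicker), and ignoring that correlation would understate
  parameter uncertainty and bias the variance estimates.

The fit is generalised least squares with the AR(1) coefficient estimated
by restricted maximum likelihood: for each candidate `rho` the data are
whitened with the closed-form AR(1) Cholesky transform and the profiled
restricted log-likelihood is evaluated; a bounded scalar search over
`rho` in (-0.99, 0.99) (tolerance 1e-6) maximises it. With `rho` fixed at
0 this reproduces ordinary least squares exactly, which the tests use as
an oracle; an independent GLS implementation (`nlme::gls` with an AR(1)
correlation structure) agrees with the in-package fit on simulated data
and serves as a cross-check, not as the implementation.

Two details deserve a note:

* **Truncated-power spline basis and rank.** With `K` cycles the knots
  are `0..K`, giving hinge columns `t, (t-1)+, ..., (t-K+1)+`; the hinge
  at the final knot is identically zero on the sampled range and any
  redundant column is dropped by a QR rank check, so the design always
  has full column rank (8 columns for three cycles). Samples never reach
  the final knot because frame `i` of a cycle spanning `[s, e)` gets
  `t = k + (i-s)/(e-s)`, accumulating one unit per cycle.
* **Phase convention.** Writing the periodic component as
  `a0 + sum A_n sin(2*pi*n*t + phi_n)` requires `phi_n = atan2(a_n,
  b_n)`; the textbook shorthand `atan(b/a)` is not consistent with the
  sine form. Any fixed convention would do — PWV depends only on phase
  *differences* along the vessel — but the chosen one makes the
  sine-cosine and amplitude-phase forms agree pointwise to 1e-10, which
  is tested. Degenerate harmonics (`a_n = b_n = 0`) get phase 0 and a
  flag. Adjusted R-squared is computed on the whitened scale, where the
  least squares geometry the statistic assumes actually holds.

The HRWA (harmonic regression wave amplitude, the fitted periodic
component's peak-to-trough range over one cycle) is located on a
1024-point grid refined by local optimisation (tolerance 1e-8 in `t`); it
is invariant to the intercept and the spline component.

## From phases to a velocity

The pixel phases along the in-disc centreline are unwrapped sequentially
(the arctangent is only defined modulo 2*pi; consecutive differences are
kept in (-pi, pi]) and normalized to zero at the origin pixel. A loess
curve (local quadratic, tricube weights, span 0.5 — reproducing
polynomials up to degree 2 exactly) smooths the profile *only* to locate
extrema; the velocity line is always fitted to the raw phases, so
smoothing guides segmentation without biasing the slope.

Observed profiles fall steeply near the disc centre (where pulsation
amplitude peaks) and then turn upward. The analysis segment is the closed
interval from the first local phase maximum to the following first local
minimum, with the origin counting as a boundary maximum when the curve
falls from the start. Two refinements proved necessary:

* **Orientation.** A wave travelling *toward* the disc centre mirrors the
  profile (rising, then falling), and a maximum-to-minimum rule applied
  to such a profile can only latch onto noise wiggles. The global shape
  of the smoothed curve therefore decides the orientation first: forward
  (down-then-up) when the global maximum precedes the global minimum,
  reversed otherwise, with the mirrored minimum-to-maximum rule — and a
  negative, inward velocity — in the reversed case.
* **Degenerate pairs.** An extremum pair spanning fewer than 3 points
  cannot support the least squares line and is skipped. Monotone profiles
  have no admissible pair in either orientation and raise a "segment
  undetectable" error rather than fabricating a velocity. Local extrema
  are strict sign changes of first differences with plateau runs
  collapsed to their midpoints; no prominence threshold is applied by
  default.

Whether the HRWA attains its maximum inside the selected segment is
reported as a quality flag but never enforced. Segments shorter than 10
points trigger a low-SNR warning: the slope's standard error scales
inversely with segment length and with the per-pixel phase precision, so
high speeds (small `|beta|`) on short segments are intrinsically the
least precise regime — visible in the simulator sweeps, where relative
error at 60 mm/s is several times that at 5 mm/s under identical noise.

## Geometry and calibration

The vein mask (drawn manually on the temporal mean image, which the
pipeline exports) is reduced to a one-pixel centreline by Zhang–Suen
morphological thinning, implemented in-package; the thinning graph is
then ordered as the geodesically longest 8-connected path from the
skeleton pixel nearest the disc centre (side branches are pruned
implicitly), using unit weights for axial and `sqrt(2)` for diagonal
steps. Pixel size comes from equating the disc mask's vertical pixel
extent to the OCT-measured disc diameter in mm; the disc centre defaults
to the mask centroid. All coordinates are 0-based `(row, col)` with rows
increasing downward.

One numerical choice matters for accuracy: a discrete 8-connected path
over-estimates the length of oblique curves by up to ~8% (the staircase
effect), which would propagate directly into the velocity. Geodesic
distances are therefore measured on a locally smoothed copy of the path
(centered moving average of the coordinates, half-window 2 pixels).
Axial and 45-degree paths are collinear and unchanged — steps remain
exactly 1 and `sqrt(2)` pixels — while staircase inflation on oblique
paths essentially vanishes, which the noiseless end-to-end recovery test
(<2% error) confirms.

## Preprocessing

Sharpness is the standard deviation of the Laplacian-of-Gaussian
filtered frame (`sigma` = 2 px by default — the vessel-edge scale in a
200–300 px disc crop; the kernel is zero-sum, so the score ignores
constant offsets). Frames below 75% of the sharpest frame's score are
replaced by the temporally nearest sharp frame (earlier frame on ties),
before alignment, without changing the frame count or cycle partition.

Registration to the sharpest frame proceeds translation → rigid →
affine. The translation stage uses FFT phase correlation with parabolic
subpixel refinement; the rigid and affine stages refine by direct
optimisation (Nelder–Mead) of the mean squared intensity difference on a
strided central grid, each stage starting from the previous one and
falling back to it if refinement fails to improve the objective. The
contract — verified against the simulator's injected motion — is
recovery of known translations/rotations/affine jitter to well under
0.5 px mean centreline displacement. Warping uses bilinear interpolation
with edge replication, so alignment can never introduce zeros that the
log transform would see. Zero intensities in the data itself are clamped
to one count (8-bit convention) and counted in the QC output.

## The simulator

`simulation_config()` / `render_video()` implement the forward model the
pipeline inverts: a dark vessel of baseline radius 4 px on a brighter
fundus with a circular disc, blood-column thickness
`2*sqrt(R(x,t)^2 - r^2)` through the cylinder, Beer–Lambert attenuation
(absorbance 8.5 /mm, giving ~50% centreline contrast), a Gaussian
pulsation-amplitude envelope peaking 0.1 mm from the origin (maximum
pulsation sits near the disc centre), 15% peak radius oscillation with a
30% second harmonic, camera jitter, blur events, and stationary AR(1)
pixel noise (marginal SD 0.004 ≈ one 8-bit count, temporal correlation
0.3) with optional 8-bit quantization. Defaults — 25 fps, three 0.8 s
cycles, 0.01 mm/px, disc radius 0.55 mm — put the centreline path length
and phase-sampling interval in the range typical of real optic-disc vein
segments.

The travelling wave is imposed through a piecewise-linear phase field:
slope `-2*pi/(c*Ts)` out to a turning point at 0.35 mm, and the
opposite-direction slope beyond it. This reproduces the down-then-up
profile shape seen in real veins while keeping the pre-turn phase
*exactly* linear, so the noiseless recovery error isolates the
pipeline's own numerics; a superposition of counter-propagating waves
would contaminate the segment near the turn and conflate simulator
physics with estimator error. The turn doubles as exact ground truth for
segment selection. The stored phase-by-arclength profile satisfies the
slope identity by construction, which is asserted in the tests.

What the simulator does *not* emulate: vessel diameter changes seen
edge-on (only axial thickness modulation), uneven pulsation azimuthally
around the disc, specular reflexes, saccadic tearing within a frame,
illumination drift correlated with motion, and real cardiac variability
beyond per-cycle duration differences. Passing the recovery tests
therefore shows the estimator chain is correct and noise-stable under
the stated model, not that clinical recordings will reach the same
accuracy.

## Problem sizes and runtime choices

The shipped tests use 144 x 192 px scenes, 60 frames (three 0.8 s cycles
at 25 fps), ~43 in-disc centreline pixels, wave speeds 5/20/60 mm/s with
10 noise seeds each, 100-replicate AR(1) recovery at n = 300, and
8-frame registration stacks — sizes chosen so the whole suite completes
in about a minute and a half while every stage still operates well above
its degenerate limits. `scripts/acceptance.R` re-runs the same
computations from scratch with seeds derived from `--seed`.

## Known limitations

* Cardiac-cycle boundaries are inputs; no audio processing is included.
* Disc and vein segmentation are manual by design; no automatic
  segmentation is attempted.
* The velocity uses the first harmonic only; studies in larger vessels
  suggest single-harmonic estimates can differ from multi-harmonic ones.
* Estimates at high speeds or on very short segments carry large
  relative uncertainty (the slope tends to zero); the slope standard
  error and segment length in the output should always be inspected.
* The reversed-orientation rule extends the forward selection criterion
  to inward-travelling waves; on profiles without a clear
  global down-then-up or up-then-down structure the segment is reported
  undetectable rather than guessed.
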