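---
title: "Measuring landmine-press velocity and power from oriented-box detections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring landmine-press velocity and power from oriented-box detections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lpkin)
```

## The measurement problem

In a landmine press one end of a barbell is anchored to the floor while the
athlete presses the free end along an arc. Because the anchored end is a
fixed pivot and the bar is stiff, the movement is, to a good approximation,
a planar rigid-body rotation: a single scalar angle describes the bar's
state at every instant, and one frontal camera suffices to recover it. An
object detector that outputs oriented bounding boxes (OBBs) for the bar or
its two ends turns each video frame into a handful of pixel corner
coordinates; everything from those corners to per-repetition training
metrics is deterministic geometry and signal processing, and that is what
`lpkin` implements.

The model rests on assumptions worth keeping in view: the bar is rigid (no
whip), the rotation plane is parallel to the image plane (a true 90°
frontal view), the anchor does not migrate, grip-related micro-motion is
negligible, and for force/power the load is treated as a point mass
concentrated at the moving end. Force and power are therefore *model-based
estimates*, not measurements — the package marks them as such in its JSON
outputs.

## From corners to a calibrated trajectory

For one rotated rectangle with consecutive corners $P_1..P_4$, the side
lengths $L_1 = \lVert P_1 - P_2\rVert$ and $L_2 = \lVert P_2 - P_3\rVert$
identify the long (principal) axis; the midpoints of the two opposing long
sides are the end estimates. The branch is literal: when $L_1 > L_2$ the
midpoints are $(P_1+P_4)/2$ and $(P_2+P_3)/2$, otherwise — including the
exact square tie — $(P_1+P_2)/2$ and $(P_3+P_4)/2$. The end with the
smaller image-$y$ (higher on screen) is the moving end; an exact tie
resolves to the second midpoint. When the detector emits one small box per
end instead of a single bar box, the box centres are used directly and the
vertical-position rule is kept as a consistency check: a disagreement with
the class labels logs a warning and trusts the geometry, since end labels
can swap during training but gravity does not.

Calibration uses the mean pixel distance between the two ends across the
trial, $s = L_{\mathrm{real}}/\bar L_{\mathrm{pixel}}$, which forces the
mean metre-space bar length to equal the physical bar length exactly
(2.20 m for a full Olympic bar). The pivot, by contrast, is the per-axis
*median* of the fixed-end detections: the anchored end should be
stationary, so the median suppresses detector jitter and the occasional
bad frame better than a per-frame value or a mean. All kinematics are then
computed in a y-up frame with the origin at this pivot, so pressing gives
increasing angle and positive velocity.

Real detector output has dropouts. Missing runs of up to `max_gap` frames
(default 5, i.e. 0.1 s at 50 fps — matching the granularity of the
minimum-phase rule below) are filled by linear interpolation and flagged;
longer gaps split the recording into blocks that are analysed
independently, since interpolating through a long gap would fabricate
velocity. Blocks with fewer than two frames are unusable and dropped.

## The filtering and differentiation chain

Numerical differentiation amplifies pixel noise, so the chain interleaves
smoothing and differencing in a fixed order:

1. raw metre coordinates → Savitzky–Golay smoothing (window 9 frames,
   polynomial order 3);
2. angle by four-quadrant arctangent, then phase unwrapping (add $2\pi k$
   so successive steps stay within $\pi$);
3. SG smoothing of the unwrapped angle, central difference → $\omega$;
4. $v = L\omega$, then a zero-phase (forward–backward) Butterworth
   low-pass, cutoff 6 Hz;
5. central difference of $\omega$ → $\alpha$, low-passed the same way;
6. $F = mL\alpha + mg\sin\theta$ (using the smoothed unwrapped angle),
   $P = Fv$.

Parameter meanings and defaults: the SG window (9 frames = 0.18 s at
50 fps) spans enough of a press to suppress corner noise without flattening
the velocity peak, and order 3 preserves the local cubic shape of a
minimum-jerk-like profile; the 6 Hz cutoff sits well above voluntary
movement frequencies (< 3 Hz for a pressing action) and well below the
frame-to-frame noise band; order 4 is a conventional choice for biomech
low-passes, applied forward and backward so the net phase shift — and hence
peak timing — is zero. All of these are exposed in `filter_config()` and
`run_config()` and serialise to YAML.

Numerical details that matter:

- **Zero-phase edges.** A forward–backward IIR pass needs edge handling;
  the implementation uses even-extension (mirror) padding of 20 filter
  lengths plus steady-state initial conditions, which keeps DC gain exactly
  1 and makes time-reversal symmetry hold to ~1e-12 on typical series.
- **SG edges.** Edge samples come from the polynomial fitted to the
  first/last full window, so polynomials up to the SG order are reproduced
  exactly everywhere, preserving endpoint trends in short segments.
- **Short series.** Rather than failing on short concentric phases, SG
  windows shrink to the largest valid odd length (≥ order + 2) with a
  logged warning.
- **Central differences.** Interior samples use the symmetric formula
  (exact for quadratics); the two endpoints fall back to one-sided first
  differences.
- **α from ω, not from v.** The chain differentiates the smoothed-but-not-
  low-passed $\omega$ and then low-passes $\alpha$; differentiating the
  already-low-passed $v/L$ instead is available via
  `compute_kinematics(alpha_from = "v")`. The two differ only in whether
  the 6 Hz filter is applied before or after the second derivative; the
  default keeps each derivative's noise control explicit.

One scope note on the force law. The gravitational term $mg\sin\theta$,
with $\theta$ measured from the horizontal, corresponds to a potential
$-mgL\cos\theta$; integrating $P$ over a phase therefore balances against
$mgL(\cos\theta_s - \cos\theta_e)$ plus the change in rotational kinetic
energy, and the test suite checks exactly this work–energy identity. A
derivation from first principles for a point mass on a massless rod would
put $\cos\theta$ in the tangential gravity component instead; the
$\sin\theta$ convention is retained as the field's stated form for this
movement, and users comparing against instrumented force measurements
should treat the force/power columns as a consistent internal model, not
ground truth.

## Phase segmentation and per-rep indicators

A frame is a concentric candidate when $v > 0$ (direction) and
$v > 0.5\,$m/s (significance; the two criteria overlap but both are checked
literally). Maximal candidate runs become intervals and intervals shorter
than 5 frames are discarded as transients — the run length rule applies to
the *merged* interval. An additional angle-increase criterion
(θ strictly rising across candidates) is implemented but off by default:
the velocity criteria alone reproduce the intended segmentation, and the
angle predicate's exact form is not standardised, so it is opt-in
(`require_increasing_theta = TRUE`).

Per phase, the peak of a series is the maximum of a 5-sample sliding
maximum applied to the SG-smoothed segment (the sliding maximum leaves the
global maximum unchanged; it is kept for robustness bookkeeping and
because the smoothed-peak convention travels well across implementations).
The mean is the trapezoidal time integral divided by the phase duration
$T_c = (t_e - t_s)\Delta t$ — the natural discretisation of a
time-weighted average; no finer quadrature is warranted for a
piecewise-linear interpolant of uniformly sampled data.

## The agreement battery

Validation studies of camera-based VBT systems against linear position
transducers report a standard battery, all of which `agreement_report()`
reproduces from a paired table:

- **Pearson r** with magnitude bands (≥ 0.9 very strong, 0.7–0.9 strong,
  0.5–0.7 moderate, 0.3–0.5 weak, else very weak). Bands are defined on
  |r|; the sign is reported alongside.
- **Bland–Altman**: bias = mean difference, LoA = bias ± 1.96·SD. The bias
  CI uses the t distribution; the LoA CIs use the standard approximate
  standard error $SD\sqrt{1/n + 1.96^2/(2(n-1))}$ — the exact-variance
  alternative differs negligibly at the sample sizes involved.
- **Paired t** (two-sided; identical series are handled as t = 0, p = 1
  rather than an error).
- **Paired Cohen's d**, $d_z = \bar d / s_d$. This convention is chosen
  because it is the one consistent with published agreement tables for
  this task: given a printed bias and LoA pair, $s_d$ is recoverable as
  (LoA width)/(2·1.96) and $\bar d/s_d$ reproduces the printed effect
  sizes (see `cohens_d_from_loa()` and the bundled
  `vbt_agreement_summaries()`). The band boundaries leave 0.8–0.9
  ambiguous in some published wordings; `lpkin` uses |d| ≥ 0.8 = large.
- **Deming regression** at λ = 1 (orthogonal regression), the right model
  when both methods carry comparable measurement error; the closed-form
  moment estimator is used, with leave-one-out jackknife CIs (t quantile,
  n − 2 df) — deterministic given the data, no resampling seed. Fixed
  bias ⇔ intercept CI excludes 0; proportional bias ⇔ slope CI
  excludes 1.

The repeated-trials caveat applies here as in the literature: trials from
the same athlete are pooled as if independent, which narrows CIs somewhat;
a hierarchical agreement model is out of scope.

## What the synthetic generator does and does not emulate

`simulate_press()` renders the modelled movement exactly: a rigid bar
rotating about a fixed pivot through a minimum-jerk (quintic) angular
profile — chosen because its $\omega(t)$, $\alpha(t)$ are closed-form, its
endpoints have zero velocity and acceleration like a controlled press, and
its peak rate is analytic ($\dot s_{max} = 15/8$ of the mean rate, so
$\omega_{max} = 1.875\,\Delta\theta/T$). Defaults mirror typical capture
conditions: 50 fps, 1080p canvas, pivot near the lower-left, 2.20 m bar,
40°→80° presses of 0.8 s, load 25 kg. Imperfections are limited to
i.i.d. Gaussian corner noise and whole-frame Bernoulli dropout (detector
misses affect whole frames in practice). All randomness flows through one
integer seed.

What it deliberately does not emulate: out-of-plane rotation, perspective
and lens distortion, motion blur, occlusion by the athlete, anchor
compliance, bar bend, or correlated detector error. Passing the recovery
tests therefore demonstrates that the *geometry and signal chain* are
correct under the model's own assumptions — it does not certify accuracy
on real video, which is what the published method-comparison statistics
(and the bundled summary tables) speak to.

`simulate_paired_methods()` encodes the one structural disagreement the
planar model predicts between a full-bar-length vision system and a cable
transducer attached 15 cm inboard: both observe the same angular velocity
but convert with different radii (2.20 m vs ≈ 2.05 m), so the true slope
between methods is 2.20/2.05 ≈ 1.073 — a proportional, not fixed, bias.
Peak angular velocities are drawn log-normal (meanlog log 0.95, sdlog
0.25), centring peak linear velocity near 2.1 m/s with a realistic spread
for loads of 20–35 kg, and each method adds independent Gaussian noise
(default SD 0.15 m/s, consistent with the between-method scatter reported
for such comparisons).

## Problem sizes and verification scope

The test suite runs entirely on generated data: single trials of 100–300
frames, recovery grids of 3 durations × 3 amplitudes, 20 noisy replicates
at 2 px corner noise, 100–200 replicate batches for the stochastic
agreement properties (jackknife coverage, proportional-bias detection at
n = 500 pairs). Oracles are kept independent of the implementation:
exhaustive $2\pi k$ search for unwrapping, $O(nk)$ scans for the sliding
maximum, dense-grid quadrature for time-weighted means, a numeric
perpendicular-residual minimiser for Deming at λ = 1, and direct solution
of the local least-squares system for SG coefficients.

## Known limitations

Single-bar scenes only; no camera calibration beyond one scalar scale
factor; kinematics are 2-D by construction; force/power inherit every
model assumption above; the agreement module assumes complete pairs
(exclusions are the caller's responsibility and should be limited to clear
recording errors); pooled rather than hierarchical agreement inference.
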