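---
title: "Shoulder workspace and deltoid EMG assessment: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shoulder workspace and deltoid EMG assessment: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shoulderom)
```

## The measurement problem

Single-plane shoulder goniometry misses most of what a shoulder can or
cannot do: restricted shoulders (e.g. adhesive capsulitis) lose reach in
some directions far more than others. An arm-worn IMU streaming orientation
quaternions at 100 Hz lets us measure the *whole* voluntary 3D workspace in
one short trial, and a co-mounted surface-EMG sensor ties muscle effort to
arm position. This package is the analysis side of such a device, plus a
simulator standing in for the hardware.

## Orientation model

A sample quaternion $q = q_w + i q_x + j q_y + k q_z$ (unit norm; deviations
up to $10^{-3}$ are renormalized, larger ones rejected with the offending
timestamp) maps to its rotation matrix $R(q)$. With the neutral-pose
reference $R_0$ (arm hanging at rest), the reference-relative rotation is
$R_0^{-1} R = R_0^\top R$ — the transpose is the exact inverse for
rotations and numerically stable. Tracking the body-fixed arm direction
$\mathbf a = (0,0,1)$ gives the spherical pose

$$ r = \lVert \mathbf p \rVert,\qquad
   \beta = \arccos(p_z / r),\qquad
   \alpha = \operatorname{atan2}(p_y, p_x). $$

Design choices behind this chain:

* **Body frame.** Right-handed; $+z$ along the hanging arm (so $\beta = 0$
  at rest), $+x$ anterior (flexion plane at $\alpha = 0$), $+y$ lateral
  (abduction plane at $\alpha = 90^\circ$, posterior toward
  $|\alpha| = 180^\circ$).
* **Full-quadrant azimuth.** A single-argument arctangent can only represent
  anterior azimuths; `atan2` covers all four quadrants and reduces to
  $\tan^{-1}(y/x)$ where $x > 0$.
* **Quaternion sign.** $q$ and $-q$ are the same rotation; inputs are
  canonicalized to $q_w \ge 0$ so round trips are deterministic.
* **Axial rotation.** Following one direction vector deliberately discards
  rotation of the humerus about its long axis, avoiding Codman's paradox;
  there is no Euler-angle output mode, and hence no gimbal lock — a
  1°-step great-circle sweep through $\beta = 90^\circ$ or across the
  $\alpha = \pm 180^\circ$ seam produces output steps no larger than the
  input step (verified in the test suite).
* **Azimuth sign.** $\alpha$ is signed, medial-negative / lateral-positive,
  rather than 0–360; horizontal-abduction *span* (which can exceed 180°) is
  measured on a continuity-unwrapped azimuth axis, which is why spans
  around 200° are representable as a single number.

`stream_to_poses()` uses a vectorized quaternion sandwich product that is
algebraically identical to composing `quat_to_rotmat()`,
`relative_rotation()` and `rotate_point()` per sample; the equivalence is
asserted in the tests.

## Workspace envelope and area

The envelope is the per-azimuth-bin maximum elevation, `bin_width` 5° by
default. Unvisited bins stay absent and contribute zero area — a
conservative choice; interpolation across gaps is deliberately not the
default because a bin the subject never visited is evidence of absence in a
maximal-effort protocol.

Two area definitions are supported because "deg²" is ambiguous:

* `planar` (default): $\sum_{\text{bins}} \beta_{\max} w$ — the area under
  the envelope in the $\alpha$–$\beta$ chart. Simple, and exactly
  $360 \cdot c$ for a constant envelope $c$.
* `solid_angle`: $\sum w_{\text{rad}} (1-\cos\beta_{\max})$ steradians
  scaled by $(180/\pi)^2$ — true spherical area, bounded by the full sphere
  41252.96 deg². Checked against a $10^6$-point Monte-Carlo sphere oracle.

The mode is recorded in every report. Per-plane maxima use azimuth windows
of half-width 10° around the flexion (0°) and abduction (90°) planes;
extension is the maximal elevation anywhere in the posterior sector;
horizontal abduction is the unwrapped azimuth span among samples within 10°
elevation of horizontal, capped at 360°. A plane the subject never reaches
yields `NA` rather than 0 — restricted shoulders genuinely miss planes.

The six ROM regions split elevation at 90° (lower/higher) and azimuth into
medial $(-180^\circ, 0^\circ)$, lateral $[0^\circ, 120^\circ)$ and
posterior $[120^\circ, 180^\circ]$ sectors. All of these are configurable;
the defaults are documented choices, not anatomical constants.

## EMG chain

The raw signal is rectified and smoothed in one step by a centered moving
RMS window, truncated at the stream edges. The window is 100 ms (10 samples
at 100 Hz) — standard surface-EMG envelope practice at this rate; the
acquisition hardware this emulates performed RMS on-board with an unstated
window, so the length is a free parameter. No additional filtering is
applied by default (an optional mean-subtraction high-pass is available);
inventing an unknown hardware filter would be worse than documenting its
absence. Normalization is to the within-trial maximum (%MVC), as the
measurement protocol prescribes — note the known limitation that a
within-trial maximum need not be the true maximal activation capacity.
%MVC samples are averaged over an (α, β) grid (10° cells) and summarized
per region with sample-count weighting, so the count-weighted mean of
region means always equals the global mean.

## The simulator: what it emulates and what it does not

`simulate_trial()` reproduces the measurement protocol: after 1 s at rest,
four consecutive circuits sweep azimuth across the full range (alternating
direction, constant angular speed — a subject's "comfortable speed" is not
specified, so constant speed is the neutral choice) with elevation tracking
increasing fractions (0.25, 0.5, 0.75, 1) of the subject envelope
$B(\alpha)$, with short elevation ramps at the turning azimuth; total
duration 60 s.

* The **healthy preset** $B(\alpha)$ is a periodic spline peaking near 150°
  anteriorly, ~141° in the abduction plane and ~58° posteriorly — anchors
  chosen once for face validity against healthy per-plane maxima. Its
  planar integral (~39.6k deg²) is not calibrated to any published area
  figure, because the area definition behind published deg² values is not
  itself defined; the simulator is validated by round-trip recovery, not by
  matching subject data.
* The **frozen preset** caps elevation at 70° and restricts the sweep to
  the anterior half-space, so posterior and near-horizontal planes are
  never visited: extension and horizontal-abduction maxima come out `NA`,
  and the planar area falls below half the healthy preset's.
* **Noise** is Gaussian angular jitter added independently to azimuth and
  elevation, SD 0.5° by default for trials. Jitter is applied in angle
  space rather than as composed random rotations: it keeps the error model
  interpretable in exactly the angles the validation rig reports, and
  avoids the $1/\sin\beta$ azimuth-error amplification near the pole that
  axis-random rotations would induce, which would say more about spherical
  geometry than about the sensor.
* The **EMG surrogate** activates each channel as
  $a(\alpha,\beta) = (\beta/180)^{1.2}\,(0.55 + 0.45\cos(\alpha-\mu))$
  with preferred azimuths $\mu$ = 0°/90°/160° for the anterior/middle/
  posterior sections, baseline 0.05, multiplicative noise SD 0.1 —
  strictly increasing in elevation, mirroring the empirical pattern of
  greater deltoid activity at higher elevation angles.

What the simulator does **not** model: scapulohumeral rhythm and torso
compensation, servo dynamics, electromechanical delay, realistic EMG
spectra (the surrogate emits envelope-scale amplitudes, not raw
interference patterns), or sensor drift. Passing round-trip tests therefore
demonstrates correctness of the analysis chain, not fidelity of any
hardware.

`simulate_gimbal()` emulates the servo-driven pitch/yaw validation rig:
elevation sweeps in four azimuth planes plus a horizontal-abduction sweep
(the physical rig's exact schedule is not enumerated anywhere, so this
default covers the same motion families), linear slews at 60°/s between
waypoints. `validate_gimbal()` compares recovered angles with commanded
ones; azimuth error is evaluated only at commanded elevation ≥ 15° because
azimuth is undefined at zero elevation. The pass thresholds, 3° elevation
and 2° azimuth, are the bench maxima established for the physical sensor.

## Cohort statistics

Subjects with repeat trials enter cohort statistics as their per-subject
mean; group dispersion is the sample standard deviation (n−1). That
convention is verified in the tests: it reproduces the reference cohort's
printed 27291 ± 538 deg² from the six per-subject areas, whereas a
population (n) denominator would give ≈ 491. A single-subject group gets
SD 0 with a warning. Repeatability across a subject's repeats is the
coefficient of variation, $100\,\mathrm{sd}/\mathrm{mean}$.
`compare_groups()` reports per-metric differences and reference-relative
ratios only — no inferential statistics, since none are defined for this
design. The shipped reference table gives a frozen-to-healthy planar-area
ratio of ≈ 49.7%.

## Numerical choices and problem sizes

Quaternion norm tolerance $10^{-3}$ for repair, $10^{-6}$ for rotation-
matrix orthonormality checks; `acos`/division arguments clamped to [−1, 1]
against rounding; azimuth wrapped into $(-180, 180]$ everywhere, with
seam-crossing handled by nearest-branch unwrapping. The test suite uses
1000 random quaternions for the algebra property, a $10^6$-point Monte-
Carlo oracle for solid angle, 60 s noise-free trials (6000 samples) with
2° analysis bins for envelope round trips — the 2° bin makes the
discretization bias of the per-bin maximum small relative to the 1%
area-recovery check — and 100 seeded 20 s trials for the region-contrast
property. These sizes were chosen as the smallest that make the checks
sharp.

## Known limitations

A single IMU cannot separate glenohumeral from scapular contribution, nor
detect torso compensation; within-trial MVC normalization caps every trial
at 100% by construction, so absolute effort is not comparable across
trials; the planar area definition weights all azimuths equally rather
than by solid angle (use `solid_angle` mode when geometric area is meant);
and the region sector boundaries are conventions, not anatomy.
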