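---
title: "Quantifying urethral kinematics from ultrasound cine loops"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying urethral kinematics from ultrasound cine loops}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(urokin)
```

## The measurement model

Transperineal ultrasound (TPUS) images the mid-sagittal pelvic floor while
a subject coughs, strains (Valsalva) or voluntarily contracts the pelvic
floor muscles (PMC). `urokin` treats three operator-selected urethral
segments — proximal (bladder neck), mid and distal — plus the pubis as
rigid bodies and estimates each one's planar pose in every frame. The
modelling assumptions, in decreasing order of strength:

* **Per-segment rigidity.** Within one rectangle the speckle moves as a
  rotation + translation. The urethra as a whole bends (that is exactly
  what the kink angle measures), but a 6 mm segment over 1/30 s does not
  deform appreciably. No scale or shear is fitted.
* **In-plane motion.** Out-of-plane motion decorrelates speckle; the
  tracker's forward-backward and correlation checks demote such points
  rather than guessing.
* **Rigid pubis.** The pubis is bone; tracking it estimates probe-pubis
  motion, and measuring everything in a frame anchored to it removes that
  confounder. The inferior pubic point (IPP) and tangent direction are
  clicked once on frame 0 and transported rigidly — we do not re-detect
  the bony margin per frame, since a rigid transport of a rigid structure
  is exact up to tracking error.

### Tracking

Shi-Tomasi corners (minimum structure-tensor eigenvalue, quality 0.01 of
the ROI maximum, minimum spacing 3 px) are tracked with iterative
pyramidal Lucas-Kanade flow: 21 px windows, 3 pyramid levels, convergence
at 0.01 px. These are the standard sparse-LK settings; all are exposed in
`track_settings()`. A point survives a frame step only if (a) tracking it
backward lands within 1 px of where it started and (b) the matched window
correlates with its reference (zero-mean NCC at least 0.5). Poses come
from a closed-form Procrustes fit; when any correspondence misfits by
more than 2 px, a deterministic RANSAC (2-point hypotheses, 2 px inlier
band) rejects outliers before the final least-squares refit.

Tracking is frame-to-frame rather than frame-0-to-frame-t because
speckle decorrelates over long intervals; the price is drift, which is
why the validation suite bounds absolute error against ground truth
rather than assuming it away. When fewer than half the seeded features
survive, features are re-detected inside the current (moved) rectangle
and the accumulated pose carries on unchanged.

### Coordinates and metrics

Image coordinates are raster pixels (x = column, y = row increasing
downward, 0-based); a rectangle's origin is its bottom-left corner in
anatomical display. The pelvic frame has its origin at the IPP, x along
the inferior pubic margin pointing posteriorly (IPP toward the annotated
tangent point — the annotator must click posterior to the IPP), and y
superior. The one raster-to-anatomical sign flip lives in `to_pelvic()`
and nowhere else; positive pelvic rotation is counter-clockwise with y
up.

All metrics derive from the pelvic pose series relative to frame 0 (the
rest frame): Δx, Δy, Δθ, |d|, φ = atan2(Δy, Δx) (so pure descent is
−90°), the signed kink angle ω (positive when the chain bends convex
toward anterior; the published figures distinguish convex from concave
without printing a formula, so the convention is documented here and is
mirror-consistent), and relative segmental mobility
r = (|d|_lower − |d|_upper)/Δy_rest. Design choices worth recording:

* **Maximum excursion** is defined on the proximal segment's |d| by
  default (bladder-neck descent is the clinically emphasized quantity);
  `excursion_roi` switches to mid, distal or the across-segment mean.
  Ties break to the earliest frame, and `select_trial()` picks the
  repetition with the greatest excursion.
* **φ reliability.** Below 0.1 mm of displacement the direction of d is
  numerically meaningless (tiny positional noise swings the angle), so φ
  carries an `phi_unreliable` flag there and flagged values are excluded
  from direction averages.
* **Relative mobility** is normalised by the *rest-frame* inter-segment
  y-distance, not the per-frame one, so r is a pure function of the
  displacements. Both signed r and |r| are available downstream; the sign
  convention makes proximal-dominant motion negative.
* **Δθ** is the rigid-fit rotation of the segment's ROI, not the chord
  orientation change of the segment chain.

### Statistics

`summary_stats()` reports n, mean, sample SD (n − 1), SEM, range and CV
(100·SD/|mean|, half-up integer rounding for reports — the absolute value
matters for direction metrics whose means are negative; circular
statistics are deliberately not used because the published CVs for
angular columns are plain SD/|mean| ratios, which we verified against the
printed table). `rm_anova_2x3()` fits the mixed design (group between,
maneuver within) through `stats::aov` with a subject error stratum; no
sphericity correction is applied and the result object says so. When an
effect's sum of squares is exactly zero the F statistic is reported as 0
with p = 1 rather than 0/0. `pairwise_compare()` runs pooled-variance
independent t-tests and paired t-tests, with the Bonferroni family being
exactly the set of declared contrasts — the default family of five (three
between-group, two within-group) matches the published analysis; the
published work does not state the family size m, so it is explicit and
configurable here.

## The synthetic cine generator

No imaging data accompanies the method, so validation runs against a
generator whose ground truth is known exactly.

* **Texture**: Gaussian-low-pass-filtered white noise rescaled to [0, 1],
  with σ = grain/2 so the 1/e autocorrelation length equals the grain
  scale (3 px default). This is deliberately *not* a physical speckle
  model — no beamforming, no depth dependence — because what the tracker
  consumes is a deterministic, corner-rich, decorrelating texture, and
  low-passed noise provides exactly that. Any 40 × 40 px window yields
  at least 50 trackable corners at the default detector settings.
* **Waveforms**: cough is a raised-cosine spike (0.15 s rise, 0.35 s
  rebound) preceded by a 0.5 mm anticipatory superior pre-lift with
  0.2 s lead — the pre-programmed pelvic floor "preflex"; Valsalva is a
  1.5 s smoothstep ramp to a 2 s plateau with a partial release to a 25%
  creep residual (viscoelastic loading); PMC is a superior raised-cosine
  lift whose Δx goes posterior then reverses anterior with exactly one
  zero crossing. Quantitative waveform timings are not published for this
  method, so these defaults are plausible physiological values and every
  one is a `motion_template()` parameter. The peak |d| of a trajectory
  always equals the template amplitude |(ax, ay)| (the PMC composite is
  normalised to guarantee it), which makes amplitude recovery exactly
  checkable.
* **Scene**: 384 × 384 px at 0.2 mm/px and 30 Hz (the typical acquisition
  rate), pubis anterior with the IPP at its inferior margin, the three
  urethral rectangles posterior to it spaced 18 mm apart along the
  superior-inferior axis — enough clearance that excursions up to ~12 mm
  never collide. Patches are warped rigidly with bilinear interpolation
  and blended over an 8 px cosine taper outside a 16 px rigid margin, so
  no artificial seams create spurious trackable edges, and feature
  windows near rectangle borders still sit on rigidly-moving texture.
* **Confounders**: a global sinusoidal probe motion (translation +
  rotation about the frame centre) warps the *whole* frame; the pubis
  patch moves only with it. Additive Gaussian noise (SD 0.02) is applied
  per frame. Ground truth stores the probe-free pelvic trajectories, so
  probe-motion invariance is testable by construction.
* **Cohorts**: per subject and cell, a displacement magnitude is drawn
  from a normal truncated at zero and a direction from a normal, with the
  group means and SDs taken from `reference_displacement_summary()` — the
  published 21-subject summary table — so simulated case-control studies
  carry the published effect sizes (e.g. proximal Valsalva 5.98 ± 2.01 mm
  control vs. 10.64 ± 3.69 mm SUI at n = 10/11). Segment rotation
  amplitudes are uncalibrated (nothing is published about them) and
  default to 4° ± 1.5°.

### What passing tests do and do not show

The generator reproduces the *geometry* of the measurement problem —
rigid segment motion, a rigid reference bone, global probe motion,
decorrelating texture, realistic amplitudes and frame rates — so green
tests demonstrate that the algorithm chain (detection → flow → robust
pose → frame correction → metrics → statistics) is internally correct and
meets its accuracy contracts under those conditions. They do not
demonstrate performance on clinical images: real B-mode loops contain
out-of-plane motion, shadowing, anisotropic resolution, tissue
deformation within segments and operator-dependent ROI placement, none of
which the generator emulates. Accuracy numbers here are best read as
"error added by the algorithms", a lower bound on clinical error.

## Numerical choices and degenerate inputs

* Bilinear sampling everywhere, edge-clamped; pixel centres at integer
  coordinates.
* The LK normal matrix is rejected when its determinant falls below
  1e-12 (textureless window); pose estimation refuses to run with fewer
  than 10 valid correspondences; re-seeding failure raises an error
  naming the ROI and frame.
* RANSAC uses an internal deterministic xorshift sampler seeded from the
  ROI name, so results never depend on (or disturb) the session RNG.
* Zero-variance statistical inputs are explicit: identical samples give
  t = 0, p = 1; a zero effect sum of squares gives F = 0, p = 1; a zero
  mean makes CV an error rather than Inf.
* Collinear chain origins give ω = 0; coincident adjacent origins are a
  degenerate-geometry error, as is a zero inter-segment distance.

## Problem sizes used in validation

The test-suite and acceptance runs use the generator at its default
scene (384 px, 30 Hz, noise 0.02): single default-length cines for the
tracking-accuracy and probe-invariance checks; 1000 metric-level null
cohorts for the ANOVA type-I property; and full image-level cohorts at
n = 10/11 for the group-separation property, run for a handful of seeds
with only the proximal segment tracked (the contrast under test is
proximal; the pubis is always tracked for the frame). At the published
effect size the per-seed probability of a Bonferroni-significant
proximal contrast is about 0.75, so "a majority of seeds" is the correct
expectation, not certainty — a run of five seeds fails that bar about
one time in ten even when everything is correct.

## Known limitations

* Only PNG/TIFF image stacks (with a JSON sidecar) are readable;
  multiframe DICOM and video containers must be exported to a stack
  first. Pixel spacing must be isotropic.
* The pelvic frame transports the frame-0 tangent rigidly; if the
  annotated tangent is poor, every direction metric inherits that error.
* Per-ROI rigid motion cannot represent within-segment deformation; the
  kink angle captures bending *between* segments only.
* The mixed ANOVA assumes sphericity (unchecked, as in the published
  analysis) and complete cases; subjects missing a maneuver are excluded
  by the cohort runner before testing.
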