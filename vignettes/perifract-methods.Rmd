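---
title: "Methods: fractal analysis of peri-implant bone on serial radiographs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fractal analysis of peri-implant bone on serial radiographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perifract)
```

## The problem and the measurement

After a dental implant is placed, the trabecular bone around it remodels as
masticatory load returns. On serial periapical radiographs this remodeling
shows up as a change in the *texture* of the bone rather than in its mean
brightness, and the box-counting fractal dimension (FD) of the binarized,
skeletonized trabecular pattern is the standard scalar summary of that
texture complexity. `perifract` implements the whole measurement chain —
alignment, standardized region-of-interest (ROI) extraction, the classical
preprocessing chain, box counting, and longitudinal inference — together
with a synthetic radiograph generator, because clinical radiographs of this
kind are generally not shareable and every stage therefore needs to be
testable against constructed ground truth.

## Pipeline stages and the choices behind them

### Rigid alignment

Serial periapical radiographs taken with the paralleling technique differ
by small in-plane shifts and rotations. `register_rigid()` estimates a
rigid-body transform (translation plus rotation about the image centre) by
minimizing the mean squared intensity difference over a coarse-to-fine
pyramid (mean 2×2 pooling, at least three levels, coarsest level at least
32 px). Two numerical choices matter:

* the objective is evaluated over the *valid overlap* only — pixels whose
  source location falls outside the moving image are excluded rather than
  zero-filled, so the fill value cannot drag the optimum;
* the coarsest level is seeded by an exhaustive integer grid over
  translations (±`max_shift`) followed by a 1° sweep over rotation, because
  a purely local simplex search can stall on the shallow centre of the
  similarity landscape. Each level then refines by Nelder–Mead with a
  quasi-Newton polish.

Follow-ups are registered to the patient's baseline (baseline-as-fixed; the
alternative of mutual registration would make the ROI frame depend on the
visit set). The aligned follow-up is resampled with bilinear interpolation
and analyzed in the baseline frame, so a single ROI specification per
patient-side applies to every visit. On noiseless phantoms the recovery
error over |dx|, |dy| ≤ 10 px and |θ| ≤ 5° is below 0.5 px and 0.25°
(checked in the test suite and by `scripts/acceptance.R`).

### ROI placement

ROIs are 10 px wide × 30 px tall (long axis parallel to the implant axis),
placed mesially and distally as close as possible to the first implant
thread, or at the cemento–enamel junction (CEJ) line endpoints for control
teeth. "As close as possible" is operationalized as minimal Euclidean
distance from the ROI's inner-edge midpoint (rectangle centre for CEJ
anchors) to the anchor point, subject to: the rectangle lies fully inside
the image and clears the exclusion mask — implant threads, adjacent teeth,
lamina dura, periodontal ligament, alveolar crest, root surfaces — by at
least one pixel. The search is exhaustive, so placement is deterministic
and provably distance-minimal; ties break toward the alveolar crest
(smaller row), then smaller column. Exclusion structures are supplied as a
mask (drawn by the operator or generated by the synthetic module);
automatic segmentation of anatomy is out of scope. Control-tooth ROIs are
given no fixed apical offset from the CEJ line — nearest admissible
placement decides — since no convention is established. Coordinates are
0-based with half-open extents, and by package convention the mesial side
is the lower-column side of the implant.

### The preprocessing chain

`run_chain()` applies, in fixed order: Gaussian blur, subtraction of the
blur from the original plus a 128 offset, thresholding at 128, one erosion
and one dilation (3×3 square), outline, and Zhang–Suen skeletonization.
The provenance of every mask records exactly these eight steps; permuting
them is not representable. Numerical decisions:

* **Blur kernel.** "Kernel size 35" is interpreted as a 35×35 discrete
  kernel with σ = 35/6 ≈ 5.83 px (±3σ support convention). Historical
  ImageJ-era reimplementations disagree on the parameterization (radius vs
  kernel vs σ), so σ is exposed as an argument; the brightness-shift
  invariance below holds under any σ. The border is extended by
  half-sample reflection, which conserves total intensity and keeps the
  operator symmetric.
* **Intermediate precision.** Blur and subtraction are computed in floating
  point; the only quantization is the binarization itself, avoiding
  double-rounding artifacts.
* **Threshold side and tolerance.** Foreground (trabecular bone, the
  locally bright phase) is `value ≥ 128 − 1e-6`. The ≥ convention makes a
  perfectly flat field — which lands at exactly 128 after subtraction —
  foreground; the 1e-6 gray-level tolerance absorbs floating-point residue
  on such plateaus while leaving genuinely darker values (127.9) as
  background. This is also what makes the chain *bit-identical* under
  global brightness shifts of the input (up to saturation), the property
  that underwrites robustness to exposure and dose differences between
  visits.
* **Morphology border.** Erosion pads beyond the patch border with
  foreground, dilation with background. On a 10-px-wide window a
  background-padded erosion would strip the entire border ring — a third of
  the patch — turning the window edge, which carries no information about
  bone, into the dominant signal.
* **Skeletonization.** Zhang–Suen two-subiteration thinning (the method
  itself names no algorithm); outputs are verified 1-px thin (no 2×2
  foreground block) across random phantoms.

### Box counting

`box_count()` overlays grids of tile sizes 2, 3, 4, 6, 8, 12, 16, 32, 64 px
anchored at the ROI's top-left corner (no origin averaging, matching the
classical ImageJ counter; grid-origin sensitivity is bounded and tested on
the Sierpinski carpet). Partial edge tiles count when they contain
foreground. FD is minus the slope of the unweighted least-squares fit of
log(count) on log(size); the log base cancels in the slope.

Tile sizes larger than the mask degenerate to a single tile and would
contribute constant `(log s, 0)` points. These are dropped by default
(`drop_oversize = TRUE`): on a 10×30 ROI the degenerate 32 and 64 px points
cap the attainable FD at about 1.37, well below the range reported for real
trabecular ROIs of this size, so a counter that includes them cannot have
produced the published clinical values. The faithful-but-odd variant that
keeps every listed size remains available via `drop_oversize = FALSE`.

An empty mask raises an explicit undefined-FD error rather than returning
0, and `fd_visit()` flags a visit incomplete instead of silently averaging
when one side fails; the per-visit FD is otherwise the exact arithmetic
mean of the mesial and distal estimates.

The estimator is validated against constructions with known dimension:
a point (FD 0), a 64-px line (1), a filled square (2, with the closed-form
counts 1024, 256, 64, 16, 4, 1), and a level-5 Sierpinski carpet
(log 8 / log 3 ≈ 1.8928, recovered exactly on power-of-3 grids because the
counts 8^(5−k) are exactly self-similar, and within 0.05 on the standard
clinical tile list).

### Longitudinal statistics

Per-visit mean FD is modeled with time as a categorical factor (months
0/3/6/12, baseline reference) and a per-patient random intercept — the
natural specification for an unbalanced panel in which patients attend
different subsets of visits. Two routes share one interface
(`fit_longitudinal()`):

* `method = "lmm"` — a linear mixed model (lme4, REML), the default;
* `method = "gee"` — a Gaussian generalized estimating equation with
  exchangeable working correlation and robust sandwich covariance,
  implemented in-package, whose output is the classical "Wald χ²"
  presentation.

Both report joint Wald χ² tests per fixed effect and the pairwise baseline
contrasts (0 vs 3, 0 vs 6, 0 vs 12); with treatment coding each time
coefficient *is* its baseline contrast. Pairwise p-values are reported
unadjusted, with a Holm-adjusted column alongside. Age enters continuous;
study and control cohorts are fitted separately. Between-sex comparisons
use Welch's t-test by default (Student's as an option), with the n−1
denominator for all SDs. Under null simulations at the reference panel
structure the per-contrast type-I error is within 0.03–0.07 at nominal
0.05, and injected time and jaw effects are recovered with bias well below
10% of the effect size (both recomputed by the acceptance script).

## The synthetic-data module

### What it emulates

`trabecular_phantom()` renders a bright bony matrix crossed by thin dark
marrow channels: two band-limited Gaussian random fields (log-normal radial
amplitude bands centred at wavelengths of 16 px and 10 px at the nominal
300 dpi scale) are synthesized spectrally, and the intensity is
`log(|field| + 0.02)` standardized to the requested contrast — a
log-attenuation-style mapping whose near-zero level sets become 1–3 px dark
channels, the radiographic appearance of marrow spaces between trabeculae.
The single complexity knob (`hurst`, dimensionless in (0, 1), lower = more
complex) weights the finer channel family into the field.

The knob's mapping was calibrated once, before the acceptance checks were
wired up, by simulating the *full* pipeline over independent seed blocks:
a naive scale-free fractional-Brownian texture fails as a phantom here
because the chain's 3×3 opening erases all sub-3-px foreground — exactly
the scales that carry a rough field's level-set dimension — and inverts the
intended complexity ordering. With the calibrated two-band channel model,
the median pipeline FD decreases strictly in the knob (roughly 1.51 / 1.47
/ 1.43 at 0.2 / 0.5 / 0.8) and individual phantoms stay within the
clinically plausible 1.30–1.90 band.

`make_series()` turns a phantom into a longitudinal cohort: each patient
keeps a fixed anatomy (the white-noise realizations and the pixel-noise
field), and per visit the knob moves by a trajectory offset, a jaw offset
and a patient-level deviation; the rendered image then receives rigid
jitter (SD 3 px and 2° by default — no published estimate of inter-visit
misalignment exists, so these are exposed parameters) and a global
brightness shift (SD 5 gray levels). Because the texture field is
re-standardized before scaling, complexity drift does not change luminance:
the longitudinal signal travels through FD, not brightness. Baseline visits
are never jittered, so follow-ups register back to them. The default visit
panel (`reference_panel()`) is the package's reference cohort: 77 patients,
215 visit records, time margins 77/31/64/43 — the unbalanced structure that
motivates mixed models.

For statistical calibration at hundreds of replicates,
`simulate_fd_panel()` draws FD records directly from the corresponding
mixed model (grand mean 1.59, between-patient SD 0.19, within-patient SD
0.05 by default) on any panel; rendering 500 image cohorts would test the
random number generator more than the statistics.

### What it does not emulate

Radiographic physics (beam geometry, scatter, heel effect), scanner
artefacts, anatomy other than a threaded implant silhouette, cone-cutting,
and any misalignment beyond rigid in-plane jitter. Passing tests on
phantoms therefore demonstrate that the *measurement chain* is correct and
calibrated — not that FD separates clinical groups on real radiographs.

## Problem sizes in the test suite

Phantoms are 160×160 px; monotonicity sweeps use 20–25 seeds per knob
value; registration recovery uses six transform draws per phantom; null
calibration uses 1000–2000 replicates of the 215-record panel, power 300
replicates at 40 patients, and jaw-effect recovery 200 replicates at 200
visits. These sizes were chosen so each property is measured with
Monte-Carlo error well inside its acceptance margin.

## Known limitations

* FD values from 10×30 ROIs are strongly window-limited: the OLS fit mixes
  genuinely fractal scaling (2–8 px) with near-saturated coarse tiles, so
  absolute FDs are comparable only within a fixed ROI size and tile list —
  a caveat that applies equally to the clinical literature this pipeline
  mirrors.
* The grid origin is fixed at the ROI corner; origin averaging would reduce
  translation sensitivity at the cost of comparability with the classical
  counter.
* The GEE route estimates a single exchangeable correlation; serial
  correlation structures are out of scope.
* Whether the box counter of the classical chain counted partial edge
  tiles on small ROIs is not documented anywhere; partial tiles count
  here, which is a comparability caveat against other implementations.
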