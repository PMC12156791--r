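# perifract

Fractal analysis of peri-implant trabecular bone on serial periapical
radiographs.

After implant placement, returning masticatory load remodels the
surrounding trabecular bone. On serial periapical radiographs this shows up
as a change in texture complexity rather than in brightness, and the
box-counting fractal dimension (FD) of the binarized, skeletonized
trabecular pattern is the standard scalar summary of that complexity.
`perifract` is for researchers who want that measurement as a tested,
reproducible pipeline rather than a manual ImageJ workflow:

* **Rigid alignment** of each follow-up radiograph to its baseline
  (translation + rotation, pyramid least-squares), so one region of
  interest (ROI) per patient-side applies to every visit.
* **Standardized ROI placement**: the 10 × 30 px mesial and distal windows
  as close as possible to the first implant thread (or to the
  cemento–enamel junction line for control teeth), provably
  distance-minimal subject to an anatomical exclusion mask.
* **The classical preprocessing chain**: Gaussian blur (35 px kernel) →
  subtract + 128 → threshold at 128 → erode → dilate → outline →
  Zhang–Suen skeletonize. The chain is bit-invariant to global brightness
  shifts, which is what makes FD robust to exposure differences between
  visits.
* **Box-counting FD**: occupied-tile counts over the standard grid
  (2, 3, 4, 6, 8, 12, 16, 32, 64 px), FD = −slope of the ordinary
  least-squares fit of log N(s) on log s.
* **Longitudinal statistics** on the per-visit FD records: a linear mixed
  model with per-patient random intercept (or a GEE variant with
  exchangeable working correlation), Wald χ² tests and baseline time
  contrasts (0 vs 3/6/12 months), Welch t-tests between groups, and the
  standard descriptive table by sex, time and jaw.
* **A synthetic-data module**: trabecular phantom radiographs with a
  controllable complexity knob, longitudinal series with rigid and
  brightness jitter, and exact-dimension fractal fixtures (point, line,
  filled square, Sierpinski carpet) — so the whole pipeline is testable
  without patient data.

## Worked example

```r
library(perifract)

## 1. validate the FD estimator on an exact fractal
carpet <- exact_fractal("sierpinski_carpet", size = 243, level = 5)
box_count(carpet, c(3, 9, 27, 81))
#> <fd_boxcount> fd = 1.8928 (r^2 = 1.0000), 4 tile sizes, 32768 foreground px
```

The level-5 carpet has theoretical dimension log 8 / log 3 ≈ 1.8928; on
power-of-3 grids the counts are exactly self-similar, so the estimate is
exact.

```r
## 2. registration: recover a known misalignment
baseline <- trabecular_phantom(seed = 11)
moved <- resample(baseline, rigid_transform(dx = 5, dy = -3, theta = 2))
register_rigid(moved, baseline)
#> <rigid_transform> dx=-4.9861 px, dy=3.3192 px, theta=-2.0085 deg
#>   objective (MSE): 153.2691
```

The recovered transform is the inverse of the applied jitter to within a
fraction of a pixel and of a degree.

```r
## 3. longitudinal demo: complexity gain at 12 months on an aligned series
panel <- tibble::tibble(
  patient_id = rep(sprintf("P%02d", 1:12), each = 2),
  timepoint  = rep(c(0, 12), 12)
)
run <- run_pipeline(list(
  scenario = list(panel = panel, complexity_trajectory = c("12" = -0.35),
                  misalignment_sd = c(0, 0), seed = 1),
  seed = 1
))
head(run$records[, c("patient_id", "timepoint", "fd_mesial", "fd_distal", "fd_mean")], 4)
#> # A tibble: 4 × 5
#>   patient_id timepoint fd_mesial fd_distal fd_mean
#>   <chr>          <dbl>     <dbl>     <dbl>   <dbl>
#> 1 P01                0      1.46      1.49    1.47
#> 2 P01               12      1.54      1.53    1.54
#> 3 P02                0      1.42      1.49    1.46
#> 4 P02               12      1.50      1.53    1.51
run$fit
#> <fd_longfit> LMM fit: 24 visits, 12 patients; fixed effects: time, jaw
#> Joint Wald tests:
#>  effect wald_chi2 df   p_value
#>    time   30.3249  1 3.654e-08
#>     jaw    0.6662  1 4.144e-01
#> Baseline time contrasts:
#>                label estimate       se wald_chi2 df   p_value    p_holm
#>  month 0 vs month 12  0.04425 0.008035     30.32  1 3.654e-08 3.654e-08
```

The scenario injects a complexity gain at 12 months (a negative knob
offset lowers texture smoothness, hence raises FD); the pipeline measures
per-visit FD as the exact mesial/distal mean (values here around 1.45–1.55,
inside the clinically observed range) and the mixed model detects the
0-vs-12-month contrast (+0.044 FD, Wald χ² = 30.3, p < 1e-7) while the
jaw term, unset in this scenario, stays null.

`autoplot()` works on box-count results and fitted models;
`plot_fd_trajectories()` draws the per-patient FD spaghetti plot;
`tidy()`/`glance()` return the usual coefficient and one-row summaries.

## Limitations

FDs from 10 × 30 px windows are comparable only within a fixed ROI size and
tile list; the synthetic phantoms emulate trabecular texture statistics,
not radiographic physics. See the methods vignette
(`vignettes/perifract-methods.Rmd`) for the full account of the model,
parameter conventions and design decisions.
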