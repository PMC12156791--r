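Package: perifract
Title: Fractal Analysis of Peri-Implant Trabecular Bone on Serial Periapical Radiographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for monitoring peri-implant bone remodeling on
    serial periapical radiographs with box-counting fractal dimension (FD). Provides
    rigid intensity-based alignment of follow-up radiographs to baseline, standardized
    10x30-pixel mesial/distal region-of-interest placement at the first implant thread
    (or at the cemento-enamel junction for control teeth), the classical
    blur/subtract/threshold/open/outline/skeletonize preprocessing chain for trabecular
    texture, box-counting FD estimation with log-log regression, and longitudinal
    inference on the resulting per-visit FD records via linear mixed models (or a
    generalized estimating equation variant) with Wald chi-square contrasts. Because
    clinical radiographs of this kind are rarely shareable, the package includes a
    synthetic-data module: fractional-Brownian-surface bone phantoms with a rendered
    implant, longitudinal series with controllable complexity drift, rigid jitter and
    brightness jitter, and exact-dimension fractal fixtures (point, line, filled square,
    Sierpinski carpet) for validating the FD estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
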