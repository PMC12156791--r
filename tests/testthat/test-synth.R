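test_that("phantom generation is deterministic and validated", {
  a <- trabecular_phantom(seed = 5)
  b <- trabecular_phantom(seed = 5)
  expect_identical(unclass(a), unclass(b))
  c <- trabecular_phantom(seed = 6)
  expect_false(all(a == c))

  # generators must not disturb the caller's RNG stream
  set.seed(99)
  before <- rnorm(3)
  set.seed(99)
  invisible(trabecular_phantom(seed = 1))
  expect_identical(before, rnorm(3))

  expect_error(trabecular_phantom(width = 64), "96")
  expect_error(trabecular_phantom(hurst = 0), "hurst")
  expect_error(trabecular_phantom(hurst = 1.2), "hurst")
})

test_that("zero-variance parameters give a constant image", {
  ph <- trabecular_phantom(contrast = 0, noise_sd = 0, mean_gray = 77, implant = NULL)
  expect_equal(unique(as.vector(ph)), 77)
})

test_that("implant silhouette is rendered near-saturated with a threaded profile", {
  geom <- implant_geometry(radius = 10, thread_pitch = 8, top_row = 20, thread_amp = 2)
  ph <- trabecular_phantom(implant = geom, seed = 2)
  mask <- implant_mask(geom, ncol(ph), nrow(ph))
  expect_true(all(ph[mask] == 250))
  expect_false(any(mask[1:20, ])) # nothing above the collar
  # thread crests widen the profile relative to the core
  widths <- rowSums(mask)
  expect_gt(max(widths[21:120]), 2 * 10)
  expect_equal(geom$first_thread_row, 28)
})

test_that("exact fractal fixtures have the right mass and theoretical dimension", {
  pt <- exact_fractal("point", 64)
  expect_equal(sum(pt), 1)
  expect_equal(attr(pt, "theoretical_fd"), 0)

  fr <- exact_fractal("filled_rect", 64)
  expect_true(all(fr))
  expect_equal(attr(fr, "theoretical_fd"), 2)

  cp <- exact_fractal("sierpinski_carpet", 243, 5)
  expect_equal(sum(cp), 8^5)
  expect_equal(attr(cp, "theoretical_fd"), log(8) / log(3))
  # self-similarity: each occupied 3x3 cell holds 8 pixels
  expect_equal(sum(exact_fractal("sierpinski_carpet", 27, 3)), 8^3)

  expect_error(exact_fractal("sierpinski_carpet", 100, 4), "3\\^level")
  expect_error(exact_fractal("sierpinski_carpet", 81), "level")
})

test_that("reference panel reproduces the unbalanced cohort margins", {
  p <- reference_panel()
  expect_equal(length(unique(p$patient_id)), 77)
  expect_equal(nrow(p), 215)
  expect_equal(as.integer(table(p$timepoint)[c("0", "3", "6", "12")]), c(77L, 31L, 64L, 43L))
  by_pat <- split(p$timepoint, p$patient_id)
  expect_true(all(vapply(by_pat, function(tp) 0 %in% tp && length(tp) >= 2, logical(1))))
})

test_that("scenario validation enforces baseline plus a follow-up", {
  bad <- tibble::tibble(patient_id = c("A", "A", "B"), timepoint = c(0, 6, 6))
  expect_error(longitudinal_scenario(panel = bad), "baseline")
  expect_error(
    longitudinal_scenario(panel = tibble::tibble(patient_id = "A", timepoint = c(0, 0))),
    "at most once"
  )
  expect_error(
    longitudinal_scenario(panel = tibble::tibble(patient_id = character(), timepoint = numeric())),
    "nrow"
  )
})

test_that("a noise-free flat scenario yields pixel-identical visits", {
  sc <- longitudinal_scenario(
    panel = tibble::tibble(patient_id = "A", timepoint = c(0, 3, 6)),
    complexity_trajectory = c("3" = 0, "6" = 0, "12" = 0),
    misalignment_sd = c(0, 0), brightness_jitter_sd = 0, seed = 4
  )
  ser <- make_series(sc)
  imgs <- ser$images$image
  expect_true(all(imgs[[1]] == imgs[[2]]))
  expect_true(all(imgs[[1]] == imgs[[3]]))
})

test_that("series ground truth reflects the applied trajectory, jitter and jaw effect", {
  panel <- tibble::tibble(
    patient_id = rep(sprintf("P%d", 1:6), each = 2),
    timepoint = rep(c(0, 12), 6)
  )
  sc <- longitudinal_scenario(
    panel = panel,
    complexity_trajectory = c("12" = 0.2), jaw_effect = 0.1,
    misalignment_sd = c(3, 2), brightness_jitter_sd = 5, seed = 11
  )
  ser <- make_series(sc)
  tr <- ser$truth
  base <- tr[tr$timepoint == 0, ]
  fu <- tr[tr$timepoint == 12, ]
  # positive trajectory raises the complexity knob at month 12 by construction
  expect_equal(fu$hurst - base$hurst, rep(0.2, 6))
  expect_true(all(fu$true_offset == 0.2))
  # jaw effect moves the knob between jaws
  if (length(unique(tr$jaw)) == 2) {
    expect_gt(
      mean(base$hurst[base$jaw == "mandible"]),
      mean(base$hurst[base$jaw == "maxilla"])
    )
  }
  # baseline visits carry no jitter; follow-ups recorded what was applied
  expect_true(all(base$applied_dx == 0 & base$applied_theta == 0 & base$brightness_shift == 0))
  expect_true(any(fu$applied_dx != 0))
  # determinism of the whole series
  ser2 <- make_series(sc)
  expect_identical(ser$truth, ser2$truth)
  expect_true(all(ser$images$image[[3]] == ser2$images$image[[3]]))
})

test_that("series TIFF round-trip preserves pixels and metadata", {
  sc <- longitudinal_scenario(
    panel = tibble::tibble(patient_id = "A", timepoint = c(0, 6)),
    seed = 3
  )
  ser <- make_series(sc)
  dir <- withr::local_tempdir()
  write_series(ser, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(file.exists(file.path(dir, "truth.csv")))
  man <- read.csv(file.path(dir, "manifest.csv"))
  img <- read_radiograph(man$path[1])
  expect_equal(unclass(img), unclass(ser$images$image[[1]]), ignore_attr = TRUE)
})

test_that("record-level simulator honours panel structure and injected effects", {
  d <- simulate_fd_panel(seed = 1)
  expect_equal(nrow(d), 215)
  expect_equal(length(unique(d$patient_id)), 77)
  # one covariate row per patient, constant within patient
  expect_true(all(tapply(d$jaw, d$patient_id, function(x) length(unique(x))) == 1))
  # a large injected month-12 shift is visible in within-patient differences
  d2 <- simulate_fd_panel(
    panel = tibble::tibble(
      patient_id = rep(sprintf("S%d", 1:50), each = 2),
      timepoint = rep(c(0, 12), 50)
    ),
    time_effects = c("12" = 0.3), resid_sd = 0.05, seed = 2
  )
  dif <- d2$fd_mean[d2$timepoint == 12] - d2$fd_mean[d2$timepoint == 0]
  expect_gt(mean(dif), 0.25)
  expect_lt(mean(dif), 0.35)
})
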