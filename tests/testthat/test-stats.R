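test_that("two-group t-test handles the canonical cases", {
  res <- two_group_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  sep <- two_group_test(c(1, 2, 3), c(11, 12, 13))
  expect_gt(abs(sep$statistic), 10)
  expect_lt(sep$p_value, 0.001)

  # identical constant groups: t = 0, p = 1 rather than an error
  flat <- two_group_test(c(5, 5, 5), c(5, 5, 5))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  expect_error(two_group_test(c(5, 5), c(6, 6)), "constant")
  expect_error(two_group_test(1, c(1, 2)), "at least two")

  # Student variant agrees with stats::t.test pooled
  x <- rnorm(10)
  y <- rnorm(12)
  expect_equal(
    two_group_test(x, y, var_equal = TRUE)$p_value,
    t.test(x, y, var.equal = TRUE)$p.value
  )
})

test_that("t-test false-positive rate is calibrated under the null", {
  set.seed(31)
  rej <- replicate(2000, {
    t.a <- rnorm(20, 1.6, 0.2)
    t.b <- rnorm(20, 1.6, 0.2)
    two_group_test(t.a, t.b)$p_value < 0.05
  })
  expect_gt(mean(rej), 0.03)
  expect_lt(mean(rej), 0.07)
})

test_that("longitudinal study validation enforces the panel contract", {
  d <- simulate_fd_panel(seed = 1)
  dup <- rbind(d, d[1, ])
  expect_error(fit_longitudinal(dup), "at most once")
  single <- d[d$timepoint == 0, ]
  expect_error(fit_longitudinal(single), "two timepoints")
  lone <- rbind(
    d,
    tibble::tibble(
      patient_id = "LONE", timepoint = 0, jaw = "maxilla",
      sex = "male", age = 30, fd_mean = 1.5
    )
  )
  expect_error(fit_longitudinal(lone), "LONE")
  expect_error(fit_longitudinal(d, fixed_effects = "smoking"), "unknown")
})

test_that("the mixed model recovers injected time and jaw effects", {
  d <- simulate_fd_panel(
    time_effects = c("3" = -0.09, "6" = 0.01, "12" = 0.08),
    jaw_effect = 0.19, seed = 12
  )
  fit <- fit_longitudinal(d, fixed_effects = c("time", "jaw"))
  expect_s3_class(fit, "fd_longfit")
  expect_true(fit$converged)
  ct <- fit$contrasts
  expect_equal(ct$label, c("month 0 vs month 3", "month 0 vs month 6", "month 0 vs month 12"))
  expect_lt(abs(ct$estimate[1] - (-0.09)), 0.05)
  expect_lt(abs(ct$estimate[3] - 0.08), 0.05)
  expect_true(all(ct$wald_chi2 >= 0))
  expect_true(all(ct$p_value > 0 & ct$p_value <= 1))
  # jaw varies between patients, so its estimate is noisy at n = 77; use a
  # larger cohort for a sharp check of the coefficient itself
  big <- simulate_fd_panel(
    panel = tibble::tibble(
      patient_id = rep(sprintf("B%03d", 1:300), each = 2),
      timepoint = rep(c(0, 6), 300)
    ),
    jaw_effect = 0.19, seed = 13
  )
  fit_big <- fit_longitudinal(big, fixed_effects = c("time", "jaw"))
  jaw <- fit_big$coefficients$estimate[fit_big$coefficients$term == "jawmandible"]
  expect_lt(abs(jaw - 0.19), 0.06)
  # joint Wald tests cover each fixed effect
  expect_setequal(fit$effects$effect, c("time", "jaw"))
  expect_equal(fit$effects$df[fit$effects$effect == "time"], 3)
  # Holm adjustment is monotone and no smaller than the raw p-values
  expect_true(all(ct$p_holm >= ct$p_value - 1e-12))
})

test_that("the GEE route agrees with the mixed model on point estimates", {
  d <- simulate_fd_panel(time_effects = c("12" = 0.08), jaw_effect = 0.19, seed = 3)
  lmm <- fit_longitudinal(d, method = "lmm")
  gee <- fit_longitudinal(d, method = "gee")
  expect_true(gee$converged)
  expect_gt(gee$model$alpha, 0.5) # strong within-patient correlation by design
  expect_equal(gee$coefficients$estimate, lmm$coefficients$estimate, tolerance = 0.01)
  expect_equal(
    gee$contrasts$estimate, lmm$contrasts$estimate,
    tolerance = 0.01
  )
})

test_that("tidy, glance and autoplot methods work on fits", {
  d <- simulate_fd_panel(seed = 4)
  fit <- fit_longitudinal(d)
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "se", "statistic", "p.value") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$n, 215)
  expect_equal(gl$n_patients, 77)
  expect_lt(abs(gl$sd_resid - 0.05), 0.01)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("descriptive summary margins conserve the panel total", {
  d <- simulate_fd_panel(seed = 8)
  s <- summarize_study(d)
  tot <- s$n[s$factor == "total"]
  expect_equal(tot, 215)
  for (f in c("sex", "timepoint", "jaw")) {
    expect_equal(sum(s$n[s$factor == f]), tot)
  }
  expect_equal(s$mean[s$factor == "total"], mean(d$fd_mean))
  expect_equal(s$sd[s$factor == "total"], sd(d$fd_mean))
  # two-record block: n-1 denominator
  two <- summarize_study(tibble::tibble(
    patient_id = c("a", "b"), timepoint = c(0, 0),
    jaw = "maxilla", sex = "female", fd_mean = c(1.4, 1.6)
  ))
  expect_equal(two$sd[two$factor == "total"], sd(c(1.4, 1.6)))
  # single record: SD reported as 0 and flagged
  one <- summarize_study(tibble::tibble(
    patient_id = "a", timepoint = 0, jaw = "maxilla",
    sex = "female", fd_mean = 1.5
  ))
  expect_true(all(one$sd == 0))
  expect_true(all(one$sd_undefined))
  expect_equal(one$mean, one$min)
  expect_equal(one$mean, one$max)
})
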