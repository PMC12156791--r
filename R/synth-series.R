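#' Reference unbalanced visit panel
#'
#' The package's default longitudinal design: 77 patients and 215 visit
#' records over the 0/3/6/12-month schedule, with time margins of 77, 31, 64
#' and 43 visits. Every patient has the baseline visit plus at least one
#' follow-up; the panel is deliberately unbalanced (most patients have three
#' visits, some only two), which is why the stats module uses mixed models
#' rather than repeated-measures ANOVA.
#'
#' @return A tibble with columns `patient_id`, `timepoint` (months).
#' @export
#' @examples
#' nrow(reference_panel()) # 215
reference_panel <- function() {
  groups <- list(
    list(n = 24, visits = c(0, 3, 6)),
    list(n = 34, visits = c(0, 6, 12)),
    list(n = 1, visits = c(0, 3, 12)),
    list(n = 7, visits = c(0, 12)),
    list(n = 5, visits = c(0, 3)),
    list(n = 5, visits = c(0, 6)),
    list(n = 1, visits = c(0, 3, 6, 12))
  )
  id0 <- 0L
  purrr::map_dfr(groups, function(g) {
    ids <- sprintf("P%02d", id0 + seq_len(g$n))
    id0 <<- id0 + g$n
    tidyr::expand_grid(patient_id = ids, timepoint = g$visits)
  })
}

#' Define a synthetic longitudinal imaging scenario
#'
#' Describes how a cohort of serial phantom radiographs is generated: the
#' patient-by-timepoint incidence (any panel is accepted, including the
#' unbalanced [reference_panel()]), a per-visit drift in trabecular
#' complexity, a jaw effect on complexity, and the per-visit nuisance
#' processes (rigid misalignment and global brightness jitter).
#'
#' Texture complexity is controlled by the phantom's `hurst` knob (see
#' [trabecular_phantom()]); each patient's visits are synthesized from the
#' same white-noise realization with only the knob varying, so visits share
#' their anatomy and the longitudinal signal is carried by texture
#' complexity (hence fractal dimension), not by luminance.
#'
#' @param panel Tibble with `patient_id`, `timepoint` columns; every patient
#'   must include the 0-month baseline and at least one follow-up.
#' @param complexity_trajectory Named numeric vector of complexity-knob
#'   offsets by month (names among `"0","3","6","12"`); unnamed months get 0.
#'   Positive offsets lower the downstream FD. The default emulates the
#'   clinical course: a transient complexity dip at 3 months, recovery above
#'   baseline by 12 months.
#' @param jaw_effect Complexity-knob offset added for mandibular patients.
#' @param hurst Baseline complexity knob in (0, 1); lower = more complex.
#' @param patient_hurst_sd Between-patient SD of the baseline knob.
#' @param misalignment_sd Length-2 numeric `c(shift, angle)`: SDs of the
#'   inter-visit rigid jitter, pixels and degrees.
#' @param brightness_jitter_sd SD of the global per-visit brightness shift,
#'   gray levels.
#' @param width,height Image size, pixels.
#' @param mean_gray,contrast,implant Passed to the phantom renderer; see
#'   [trabecular_phantom()].
#' @param noise_sd SD of the fixed (per-patient) pixel noise field, gray
#'   levels.
#' @param prob_mandible,prob_female Covariate sampling probabilities.
#' @param age_range Uniform sampling range for age, years.
#' @param seed Integer seed; the scenario is a pure function of its fields.
#'
#' @return An object of class `longitudinal_scenario` (a list of the above).
#' @export
longitudinal_scenario <- function(panel = reference_panel(),
                                  complexity_trajectory = c("3" = 0.15, "6" = 0, "12" = -0.15),
                                  jaw_effect = 0,
                                  hurst = 0.5,
                                  patient_hurst_sd = 0.08,
                                  misalignment_sd = c(3, 2),
                                  brightness_jitter_sd = 5,
                                  width = 160, height = 160,
                                  mean_gray = 110, contrast = 25,
                                  implant = implant_geometry(),
                                  noise_sd = 2,
                                  prob_mandible = 48 / 77,
                                  prob_female = 37 / 77,
                                  age_range = c(25, 74),
                                  seed = 1) {
  stopifnot(
    is.data.frame(panel), all(c("patient_id", "timepoint") %in% names(panel)),
    nrow(panel) > 0, length(misalignment_sd) == 2, all(misalignment_sd >= 0)
  )
  if (!all(panel$timepoint %in% c(0, 3, 6, 12))) {
    stop("panel timepoints must be in {0, 3, 6, 12} months", call. = FALSE)
  }
  if (anyDuplicated(panel[c("patient_id", "timepoint")])) {
    stop("each (patient, timepoint) may appear at most once", call. = FALSE)
  }
  by_pat <- split(panel$timepoint, panel$patient_id)
  ok <- vapply(by_pat, function(tp) 0 %in% tp && length(tp) >= 2, logical(1))
  if (!all(ok)) {
    stop(
      "every patient needs the 0-month baseline and at least one follow-up; offending: ",
      paste(names(by_pat)[!ok], collapse = ", "),
      call. = FALSE
    )
  }
  traj <- c("0" = 0, "3" = 0, "6" = 0, "12" = 0)
  traj[names(complexity_trajectory)] <- complexity_trajectory
  structure(
    list(
      panel = tibble::as_tibble(panel), complexity_trajectory = traj,
      jaw_effect = jaw_effect, hurst = hurst,
      patient_hurst_sd = patient_hurst_sd,
      misalignment_sd = misalignment_sd,
      brightness_jitter_sd = brightness_jitter_sd,
      width = width, height = height, mean_gray = mean_gray,
      contrast = contrast, implant = implant, noise_sd = noise_sd,
      prob_mandible = prob_mandible, prob_female = prob_female,
      age_range = age_range, seed = seed
    ),
    class = "longitudinal_scenario"
  )
}

#' Generate a synthetic radiograph series with ground truth
#'
#' Renders every visit of a [longitudinal_scenario()]. Each patient gets a
#' fixed anatomy (white-noise realization and pixel-noise field); per visit,
#' the complexity knob is `hurst + patient deviation + trajectory offset +
#' jaw effect`, the image is rendered, then rigid jitter and a global
#' brightness shift are applied (baseline visits are never jittered, so
#' follow-ups are registered back to them). The texture field is
#' standardized to unit SD before scaling by `contrast`, so complexity drift
#' does not alter luminance.
#'
#' @param scenario A [longitudinal_scenario()].
#' @return A list of class `radiograph_series` with elements
#'   `images` (tibble: `patient_id`, `timepoint`, `image` list-column of
#'   [radiograph()]s) and `truth` (tibble with covariates, the visit's true
#'   complexity knob `hurst`, trajectory offset `true_offset`, and the
#'   applied `applied_dx`, `applied_dy`, `applied_theta`,
#'   `brightness_shift`).
#' @export
make_series <- function(scenario) {
  stopifnot(inherits(scenario, "longitudinal_scenario"))
  sc <- scenario
  pats <- unique(sc$panel$patient_id)
  rows <- with_seed(sc$seed, purrr::map(pats, function(pid) {
    tps <- sort(sc$panel$timepoint[sc$panel$patient_id == pid])
    jaw <- if (stats::runif(1) < sc$prob_mandible) "mandible" else "maxilla"
    sex <- if (stats::runif(1) < sc$prob_female) "female" else "male"
    age <- round(stats::runif(1, sc$age_range[1], sc$age_range[2]))
    hdev <- stats::rnorm(1, 0, sc$patient_hurst_sd)
    noise1 <- fbm_noise(sc$width, sc$height)
    noise2 <- fbm_noise(sc$width, sc$height)
    grain <- if (sc$noise_sd > 0) {
      matrix(stats::rnorm(sc$width * sc$height, sd = sc$noise_sd), sc$height, sc$width)
    } else {
      0
    }
    purrr::map(tps, function(tp) {
      off <- sc$complexity_trajectory[[as.character(tp)]]
      h <- sc$hurst + hdev + off +
        if (jaw == "mandible") sc$jaw_effect else 0
      h <- min(max(h, 0.05), 0.95)
      tex <- trabecular_field(noise1, noise2, sc$width, sc$height, h)
      px <- clip255(round(sc$mean_gray + sc$contrast * tex + grain))
      if (!is.null(sc$implant)) {
        px[implant_mask(sc$implant, sc$width, sc$height)] <- 250
      }
      img <- radiograph(px,
        patient_id = pid, timepoint = tp,
        jaw = jaw, sex = sex, age = age
      )
      attr(img, "implant") <- sc$implant
      if (tp == 0) {
        jit <- c(0, 0, 0)
        bshift <- 0
      } else {
        jit <- c(
          stats::rnorm(2, 0, sc$misalignment_sd[1]),
          stats::rnorm(1, 0, sc$misalignment_sd[2])
        )
        bshift <- round(stats::rnorm(1, 0, sc$brightness_jitter_sd))
        if (any(jit != 0)) {
          img <- resample(img, rigid_transform(jit[1], jit[2], jit[3]))
        }
        if (bshift != 0) {
          valid <- attr(img, "valid")
          px2 <- clip255(unclass(img) + bshift)
          img2 <- radiograph(px2,
            patient_id = pid, timepoint = tp,
            jaw = jaw, sex = sex, age = age
          )
          attr(img2, "valid") <- valid
          attr(img2, "implant") <- sc$implant
          img <- img2
        }
      }
      list(
        row = tibble::tibble(
          patient_id = pid, timepoint = tp, jaw = jaw, sex = sex, age = age,
          hurst = h, true_offset = off,
          applied_dx = jit[1], applied_dy = jit[2], applied_theta = jit[3],
          brightness_shift = bshift
        ),
        image = img
      )
    })
  }))
  flat <- purrr::flatten(rows)
  truth <- purrr::map_dfr(flat, "row")
  images <- tibble::tibble(
    patient_id = truth$patient_id,
    timepoint = truth$timepoint,
    image = purrr::map(flat, "image")
  )
  structure(list(images = images, truth = truth, scenario = sc),
    class = "radiograph_series"
  )
}

#' Write a synthetic series to disk
#'
#' Writes one uncompressed 8-bit grayscale TIFF per visit plus a ground-truth
#' CSV (`truth.csv`) and a visit manifest (`manifest.csv`).
#'
#' @param series A `radiograph_series` from [make_series()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_series <- function(series, dir) {
  stopifnot(inherits(series, "radiograph_series"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- purrr::pmap_chr(
    series$images,
    function(patient_id, timepoint, image) {
      p <- file.path(dir, sprintf("%s_m%02d.tif", patient_id, timepoint))
      write_radiograph(image, p)
      p
    }
  )
  manifest <- dplyr::mutate(series$truth[c("patient_id", "timepoint", "jaw", "sex", "age")],
    path = paths
  )
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  utils::write.csv(series$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}

#' Simulate a fractal-dimension record panel directly
#'
#' Record-level counterpart of [make_series()]: draws per-visit mean FD values
#' from a linear mixed model with a random patient intercept, for calibrating
#' and power-testing the longitudinal statistics at many replicates without
#' rendering images. Defaults describe a typical peri-implant cohort: grand
#' mean FD about 1.59 with between-patient SD 0.19 and within-patient
#' (visit-to-visit) SD 0.05.
#'
#' @param panel Patient-by-timepoint tibble, e.g. [reference_panel()].
#' @param grand_mean Baseline mean FD.
#' @param patient_sd Between-patient SD of the random intercept.
#' @param resid_sd Residual (within-patient) SD.
#' @param time_effects Named numeric vector: additive FD shift at months
#'   `"3"`, `"6"`, `"12"` relative to baseline.
#' @param jaw_effect Additive FD shift for mandible vs maxilla.
#' @param sex_effect Additive FD shift for male vs female.
#' @param age_slope FD change per year of (centred) age.
#' @param prob_mandible,prob_female,age_range Covariate sampling settings.
#' @param seed Integer seed.
#'
#' @return A tibble with `patient_id`, `timepoint`, `jaw`, `sex`, `age`,
#'   `fd_mean`.
#' @export
simulate_fd_panel <- function(panel = reference_panel(),
                              grand_mean = 1.59, patient_sd = 0.19,
                              resid_sd = 0.05,
                              time_effects = c("3" = 0, "6" = 0, "12" = 0),
                              jaw_effect = 0, sex_effect = 0, age_slope = 0,
                              prob_mandible = 48 / 77, prob_female = 37 / 77,
                              age_range = c(25, 74), seed = 1) {
  stopifnot(all(c("patient_id", "timepoint") %in% names(panel)))
  te <- c("0" = 0, "3" = 0, "6" = 0, "12" = 0)
  te[names(time_effects)] <- time_effects
  pats <- unique(panel$patient_id)
  with_seed(seed, {
    cov <- tibble::tibble(
      patient_id = pats,
      jaw = ifelse(stats::runif(length(pats)) < prob_mandible, "mandible", "maxilla"),
      sex = ifelse(stats::runif(length(pats)) < prob_female, "female", "male"),
      age = round(stats::runif(length(pats), age_range[1], age_range[2])),
      b = stats::rnorm(length(pats), 0, patient_sd)
    )
    out <- dplyr::left_join(tibble::as_tibble(panel), cov, by = "patient_id")
    out$fd_mean <- grand_mean + out$b + te[as.character(out$timepoint)] +
      jaw_effect * (out$jaw == "mandible") +
      sex_effect * (out$sex == "male") +
      age_slope * (out$age - mean(out$age)) +
      stats::rnorm(nrow(out), 0, resid_sd)
    out$b <- NULL
    out
  })
}
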