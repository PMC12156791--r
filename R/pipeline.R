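stage_wrap <- function(stage, record, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s | record %s] %s", stage, record, conditionMessage(e)),
      call. = FALSE
    )
  })
}

#' Analyze a longitudinal radiograph series
#'
#' The imaging half of the pipeline: for every patient, follow-up visits are
#' rigidly registered to the baseline and resampled into its frame; the
#' mesial and distal ROIs are placed once on the baseline (at the first
#' implant thread, clearing the exclusion mask) and the identical specs are
#' applied to every aligned visit; each patch runs through the preprocessing
#' chain and box counting, yielding one FD record per visit.
#'
#' @param series A `radiograph_series` from [make_series()], or a tibble with
#'   columns `patient_id`, `timepoint`, `image` (list of [radiograph()]s
#'   carrying an `"implant"` attribute or with `anchor` supplied).
#' @param anchor Optional [implant_geometry()]/[cej_line()] overriding the
#'   per-image `"implant"` attribute.
#' @param tile_sizes Box-counting grid, see [box_count()].
#' @param kernel_size,sigma,threshold Preprocessing parameters, see
#'   [run_chain()].
#' @param register Set `FALSE` to skip alignment (images already aligned).
#' @return A list of class `fd_analysis`: `records` (per-visit FD tibble),
#'   `roi_specs` (one spec per patient-side), `transforms` (per-visit
#'   recovered rigid transforms with objectives).
#' @export
analyze_series <- function(series, anchor = NULL,
                           tile_sizes = c(2, 3, 4, 6, 8, 12, 16, 32, 64),
                           kernel_size = 35, sigma = kernel_size / 6,
                           threshold = 128, register = TRUE) {
  images <- if (inherits(series, "radiograph_series")) series$images else tibble::as_tibble(series)
  stopifnot(all(c("patient_id", "timepoint", "image") %in% names(images)))
  records <- list()
  specs <- list()
  tfs <- list()
  for (pid in unique(images$patient_id)) {
    sub <- images[images$patient_id == pid, ]
    sub <- sub[order(sub$timepoint), ]
    if (!0 %in% sub$timepoint) {
      stop(sprintf("[stage roi | record %s] patient has no baseline visit", pid),
        call. = FALSE
      )
    }
    baseline <- sub$image[[which(sub$timepoint == 0)]]
    anc <- if (is.null(anchor)) attr(baseline, "implant") else anchor
    rois <- stage_wrap("roi", pid, place_rois(baseline, anchor = anc))
    if (is.null(rois$mesial) || is.null(rois$distal)) {
      stop(sprintf(
        "[stage roi | record %s] %s",
        pid, paste(attr(rois, "problems"), collapse = "; ")
      ), call. = FALSE)
    }
    specs[[pid]] <- roi_spec_table(rois, patient_id = pid)
    for (i in seq_len(nrow(sub))) {
      tp <- sub$timepoint[i]
      img <- sub$image[[i]]
      rec_id <- sprintf("%s/m%d", pid, tp)
      if (register && tp != 0) {
        tf <- stage_wrap("register", rec_id, register_rigid(img, baseline))
        aligned <- resample(img, tf)
      } else {
        tf <- rigid_transform(0, 0, 0)
        aligned <- img
      }
      tfs[[rec_id]] <- tibble::tibble(
        patient_id = pid, timepoint = tp,
        dx = tf$dx, dy = tf$dy, theta = tf$theta,
        objective = attr(tf, "objective") %||% NA_real_
      )
      mes <- stage_wrap("preprocess", rec_id, run_chain(
        extract_roi(aligned, rois$mesial),
        kernel_size = kernel_size, sigma = sigma, threshold = threshold
      ))
      dis <- stage_wrap("preprocess", rec_id, run_chain(
        extract_roi(aligned, rois$distal),
        kernel_size = kernel_size, sigma = sigma, threshold = threshold
      ))
      records[[rec_id]] <- stage_wrap(
        "fractal", rec_id,
        fd_visit(mes, dis, meta = radiograph_meta(img), tile_sizes = tile_sizes)
      )
    }
  }
  structure(
    list(
      records = dplyr::bind_rows(records),
      roi_specs = dplyr::bind_rows(specs),
      transforms = dplyr::bind_rows(tfs)
    ),
    class = "fd_analysis"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the arguments of [run_pipeline()].
#' @return A named list.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  yaml::read_yaml(path)
}

read_manifest_images <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    stop("manifest not found: ", manifest_path, call. = FALSE)
  }
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("path", "patient_id", "timepoint")
  miss <- setdiff(need, names(man))
  if (length(miss)) {
    stop("manifest lacks columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  base <- dirname(manifest_path)
  imgs <- purrr::map(seq_len(nrow(man)), function(i) {
    p <- man$path[i]
    if (!file.exists(p)) p <- file.path(base, man$path[i])
    if (!file.exists(p)) {
      stop(sprintf(
        "[stage io | record %s/m%s] image file missing: %s",
        man$patient_id[i], man$timepoint[i], man$path[i]
      ), call. = FALSE)
    }
    read_radiograph(p,
      patient_id = as.character(man$patient_id[i]),
      timepoint = man$timepoint[i],
      jaw = man$jaw[i] %||% NA_character_,
      sex = man$sex[i] %||% NA_character_,
      age = man$age[i] %||% NA_real_
    )
  })
  tibble::tibble(
    patient_id = as.character(man$patient_id),
    timepoint = man$timepoint, image = imgs
  )
}

#' Run the full analysis pipeline
#'
#' End-to-end orchestration with a reproducible configuration: input images
#' (a TIFF manifest or a synthetic scenario), registration, ROI placement,
#' preprocessing, box counting, descriptive statistics and the longitudinal
#' model. Identical configuration and inputs produce identical outputs; any
#' stage failure aborts with the stage name and the offending record id.
#'
#' @param config A named list (or path to a YAML file, see
#'   [load_run_config()]) with any of: `manifest` (CSV path: `path`,
#'   `patient_id`, `timepoint`, `jaw`, `sex`, `age`), `scenario` (a
#'   [longitudinal_scenario()] or a list of its arguments -- synthetic demo
#'   mode), `implant` (anchor geometry arguments applied to all patients),
#'   `tile_sizes`, `kernel_size`, `sigma`, `threshold`, `fixed_effects`,
#'   `model` (`"lmm"`/`"gee"`), `output_dir`, `seed`.
#' @return A list of class `fd_pipeline_run`: `records`, `summary`, `fit`,
#'   `roi_specs`, `transforms`, `truth` (synthetic mode only), `config`. When
#'   `output_dir` is set, also writes `fd_records.csv`, `summary.csv`,
#'   `contrasts.json`, `roi_specs.json` and `run_log.txt` there.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) config <- load_run_config(config)
  stopifnot(is.list(config))
  cfg <- utils::modifyList(
    list(
      tile_sizes = c(2, 3, 4, 6, 8, 12, 16, 32, 64),
      kernel_size = 35, sigma = NULL, threshold = 128,
      fixed_effects = c("time", "jaw"), model = "lmm",
      output_dir = NULL, seed = 1
    ),
    config
  )
  sigma <- cfg$sigma %||% (cfg$kernel_size / 6)
  truth <- NULL
  if (!is.null(cfg$scenario)) {
    sc <- cfg$scenario
    if (!inherits(sc, "longitudinal_scenario")) {
      sc$seed <- sc$seed %||% cfg$seed
      sc <- do.call(longitudinal_scenario, sc)
    }
    series <- make_series(sc)
    truth <- series$truth
  } else if (!is.null(cfg$manifest)) {
    series <- read_manifest_images(cfg$manifest)
  } else {
    stop("config needs either `scenario` or `manifest`", call. = FALSE)
  }
  anchor <- if (!is.null(cfg$implant)) do.call(implant_geometry, cfg$implant) else NULL
  analysis <- analyze_series(series,
    anchor = anchor, tile_sizes = cfg$tile_sizes,
    kernel_size = cfg$kernel_size, sigma = sigma, threshold = cfg$threshold
  )
  recs <- analysis$records
  summary_tbl <- summarize_study(recs)
  # factor effects need at least two observed levels to be estimable
  fe <- cfg$fixed_effects
  for (v in intersect(fe, c("jaw", "sex"))) {
    if (length(unique(stats::na.omit(recs[[v]]))) < 2) fe <- setdiff(fe, v)
  }
  fit <- tryCatch(
    fit_longitudinal(dplyr::filter(recs, .data$complete),
      fixed_effects = fe, method = cfg$model
    ),
    error = function(e) {
      warning("longitudinal fit skipped: ", conditionMessage(e), call. = FALSE)
      NULL
    }
  )
  out <- structure(
    list(
      records = recs, summary = summary_tbl, fit = fit,
      roi_specs = analysis$roi_specs, transforms = analysis$transforms,
      truth = truth, config = cfg
    ),
    class = "fd_pipeline_run"
  )
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(recs, file.path(cfg$output_dir, "fd_records.csv"), row.names = FALSE)
    utils::write.csv(summary_tbl, file.path(cfg$output_dir, "summary.csv"), row.names = FALSE)
    jsonlite::write_json(analysis$roi_specs,
      file.path(cfg$output_dir, "roi_specs.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA
    )
    if (!is.null(fit)) {
      jsonlite::write_json(fit$contrasts,
        file.path(cfg$output_dir, "contrasts.json"),
        dataframe = "rows", auto_unbox = TRUE, digits = NA
      )
    }
    writeLines(
      c(
        sprintf("perifract %s", as.character(utils::packageVersion("perifract"))),
        sprintf("run at: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
        sprintf("seed: %s", cfg$seed),
        sprintf("tile sizes: %s", paste(cfg$tile_sizes, collapse = ", ")),
        sprintf("blur: kernel %d px, sigma %.4f px", cfg$kernel_size, sigma),
        sprintf("threshold: %g (foreground >= threshold - 1e-6)", cfg$threshold),
        sprintf("model: %s; fixed effects: %s", cfg$model, paste(cfg$fixed_effects, collapse = ", ")),
        sprintf("visits analyzed: %d", nrow(recs))
      ),
      file.path(cfg$output_dir, "run_log.txt")
    )
  }
  out
}

#' @export
print.fd_pipeline_run <- function(x, ...) {
  cat(sprintf(
    "<fd_pipeline_run> %d visits, %d patients\n",
    nrow(x$records), length(unique(x$records$patient_id))
  ))
  if (!is.null(x$fit)) print(x$fit)
  invisible(x)
}

#' @importFrom rlang .data
NULL
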