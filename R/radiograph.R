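#' Construct a radiograph object
#'
#' A radiograph is an 8-bit grayscale image (stored as an integer-valued
#' numeric matrix, row-major with the origin at the top-left corner and
#' 0-based pixel coordinates in all user-facing APIs) together with the
#' acquisition and patient metadata the longitudinal analysis needs.
#'
#' @param pixels Numeric matrix of gray levels in `[0, 255]`. Values are
#'   rounded to integers on construction.
#' @param dpi Scan resolution metadata (dots per inch); informational only.
#' @param patient_id Patient identifier (character or integer).
#' @param timepoint Visit time in months; one of 0, 3, 6, 12 (or `NA`).
#' @param jaw `"maxilla"` or `"mandible"` (or `NA`).
#' @param sex `"female"` or `"male"` (or `NA`).
#' @param age Age in years (or `NA`).
#'
#' @return An object of class `radiograph`: the pixel matrix with metadata
#'   stored in attributes, retrievable with [radiograph_meta()].
#' @export
#' @examples
#' r <- radiograph(matrix(128, 96, 96))
#' dim(r)
radiograph <- function(pixels, dpi = 300, patient_id = NA_character_,
                       timepoint = NA_real_, jaw = NA_character_,
                       sex = NA_character_, age = NA_real_) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(pixels) < 1 || ncol(pixels) < 1) {
    stop("radiograph must be at least 1x1", call. = FALSE)
  }
  px <- round(pixels)
  if (anyNA(px) || min(px) < 0 || max(px) > 255) {
    stop("pixel values must be finite and in [0, 255]", call. = FALSE)
  }
  if (!is.na(timepoint) && !timepoint %in% c(0, 3, 6, 12)) {
    stop("`timepoint` must be one of 0, 3, 6, 12 months", call. = FALSE)
  }
  if (!is.na(jaw) && !jaw %in% c("maxilla", "mandible")) {
    stop('`jaw` must be "maxilla" or "mandible"', call. = FALSE)
  }
  if (!is.na(sex) && !sex %in% c("female", "male")) {
    stop('`sex` must be "female" or "male"', call. = FALSE)
  }
  structure(px,
    class = c("radiograph", "matrix", "array"),
    dpi = dpi,
    patient_id = patient_id, timepoint = timepoint,
    jaw = jaw, sex = sex, age = age
  )
}

#' Metadata of a radiograph
#'
#' @param x A [radiograph()].
#' @return A one-row tibble with `patient_id`, `timepoint`, `jaw`, `sex`,
#'   `age`, `dpi`, `width`, `height`.
#' @export
radiograph_meta <- function(x) {
  stopifnot(inherits(x, "radiograph"))
  tibble::tibble(
    patient_id = attr(x, "patient_id"),
    timepoint = attr(x, "timepoint"),
    jaw = attr(x, "jaw"),
    sex = attr(x, "sex"),
    age = attr(x, "age"),
    dpi = attr(x, "dpi"),
    width = ncol(x),
    height = nrow(x)
  )
}

#' @export
print.radiograph <- function(x, ...) {
  m <- radiograph_meta(x)
  cat(sprintf(
    "<radiograph> %dx%d px, %g dpi, patient=%s, t=%s mo, jaw=%s\n",
    m$width, m$height, m$dpi, m$patient_id, format(m$timepoint), m$jaw
  ))
  invisible(x)
}

#' Read an 8-bit grayscale TIFF radiograph
#'
#' @param path Path to a TIFF file.
#' @inheritParams radiograph
#' @return A [radiograph()].
#' @export
read_radiograph <- function(path, patient_id = NA_character_,
                            timepoint = NA_real_, jaw = NA_character_,
                            sex = NA_character_, age = NA_real_, dpi = 300) {
  img <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(img)) == 3) img <- img[, , 1] # drop extra channels
  radiograph(round(img * 255),
    dpi = dpi, patient_id = patient_id,
    timepoint = timepoint, jaw = jaw, sex = sex, age = age
  )
}

#' Write a radiograph as an uncompressed 8-bit grayscale TIFF
#'
#' @param x A [radiograph()] (or numeric matrix in `[0, 255]`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_radiograph <- function(x, path) {
  m <- unclass(x)
  attributes(m) <- list(dim = dim(m))
  tiff::writeTIFF(m / 255, path, bits.per.sample = 8L, compression = "none")
  invisible(path)
}

# Evaluate `expr` under a fixed RNG seed without touching the caller's RNG
# stream (all generators in this package are pure functions of their seed).
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

clip255 <- function(x) pmin(pmax(x, 0), 255)
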