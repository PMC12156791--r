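#' Binary skeleton mask
#'
#' Container for the binarized, skeletonized trabecular pattern that feeds
#' box counting, or for an exact-dimension validation fixture. The provenance
#' attribute records the ordered processing steps that produced the mask.
#'
#' @param pixels Logical matrix; `TRUE` is foreground (trabecular bone).
#' @param provenance Character vector of applied step names, in order.
#' @param params Optional named list of step parameters.
#' @return An object of class `skeleton_mask`.
#' @export
skeleton_mask <- function(pixels, provenance = character(), params = list()) {
  if (!is.matrix(pixels) || !is.logical(pixels)) {
    stop("`pixels` must be a logical matrix", call. = FALSE)
  }
  structure(pixels,
    class = c("skeleton_mask", "matrix", "array"),
    provenance = provenance, params = params
  )
}

#' @export
print.skeleton_mask <- function(x, ...) {
  cat(sprintf(
    "<skeleton_mask> %dx%d px, %d foreground (%.1f%%)\n",
    ncol(x), nrow(x), sum(x), 100 * mean(x)
  ))
  prov <- attr(x, "provenance")
  if (length(prov)) cat("  provenance:", paste(prov, collapse = " > "), "\n")
  invisible(x)
}

#' Exact-dimension fractal fixtures
#'
#' Constructs binary sets with known (theoretical) box-counting dimension, used
#' to validate the fractal-dimension estimator: a single point (dimension 0), a
#' horizontal line (1), a filled square (2), and the Sierpinski carpet
#' (log 8 / log 3, about 1.8928).
#'
#' @param kind One of `"point"`, `"line"`, `"filled_rect"`,
#'   `"sierpinski_carpet"`.
#' @param size Side length in pixels. For the carpet, `size` must equal
#'   `3^level`.
#' @param level Iteration depth; required for the carpet, ignored otherwise.
#'
#' @return A [skeleton_mask()] with attribute `"theoretical_fd"`.
#' @export
#' @examples
#' carpet <- exact_fractal("sierpinski_carpet", size = 27, level = 3)
#' sum(carpet) # 8^3
exact_fractal <- function(kind = c("point", "line", "filled_rect", "sierpinski_carpet"),
                          size, level = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(size), size >= 1)
  size <- as.integer(size)
  px <- switch(kind,
    point = {
      m <- matrix(FALSE, size, size)
      m[ceiling(size / 2), ceiling(size / 2)] <- TRUE
      m
    },
    line = {
      m <- matrix(FALSE, size, size)
      m[ceiling(size / 2), ] <- TRUE
      m
    },
    filled_rect = matrix(TRUE, size, size),
    sierpinski_carpet = {
      if (is.null(level)) stop("`level` is required for the carpet", call. = FALSE)
      if (size != 3^level) {
        stop(sprintf(
          "carpet needs size = 3^level; got size %d with level %d (3^level = %d)",
          size, level, 3^level
        ), call. = FALSE)
      }
      cell <- matrix(1, 3, 3)
      cell[2, 2] <- 0
      m <- matrix(1, 1, 1)
      for (i in seq_len(level)) m <- kronecker(m, cell)
      m > 0
    }
  )
  fd <- switch(kind,
    point = 0, line = 1, filled_rect = 2,
    sierpinski_carpet = log(8) / log(3)
  )
  out <- skeleton_mask(px, provenance = paste0("exact_fractal:", kind))
  attr(out, "theoretical_fd") <- fd
  out
}
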