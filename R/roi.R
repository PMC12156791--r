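#' Region-of-interest specification
#'
#' A fixed analysis window, by default the standard 10 (wide) x 30 (tall)
#' pixel rectangle with its long axis parallel to the implant axis.
#' Coordinates are 0-based with half-open extent
#' `[x, x + width) x [y, y + height)`; one spec per patient-side is defined on
#' the baseline image and reused unchanged on every aligned follow-up.
#'
#' @param x,y Column and row of the top-left corner (0-based).
#' @param width,height Window size in pixels.
#' @param side `"mesial"` or `"distal"`.
#' @param anchor `"implant_first_thread"` or `"cej_line"`.
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(x, y, width = 10, height = 30,
                     side = c("mesial", "distal"),
                     anchor = c("implant_first_thread", "cej_line")) {
  side <- match.arg(side)
  anchor <- match.arg(anchor)
  stopifnot(x >= 0, y >= 0, width >= 1, height >= 1)
  structure(
    list(
      x = as.integer(x), y = as.integer(y),
      width = as.integer(width), height = as.integer(height),
      side = side, anchor = anchor
    ),
    class = "roi_spec"
  )
}

#' @export
print.roi_spec <- function(x, ...) {
  cat(sprintf(
    "<roi_spec> %s %dx%d at (x=%d, y=%d), anchor=%s\n",
    x$side, x$width, x$height, x$x, x$y, x$anchor
  ))
  invisible(x)
}

#' Cemento-enamel junction reference line
#'
#' Anchor geometry for control teeth: the line connecting the mesial and
#' distal CEJ points. Coordinates are 0-based `(x, y)` pixels.
#'
#' @param mesial,distal Length-2 numeric vectors `c(x, y)`.
#' @return An object of class `cej_line`.
#' @export
cej_line <- function(mesial, distal) {
  stopifnot(length(mesial) == 2, length(distal) == 2)
  structure(list(mesial = mesial, distal = distal), class = "cej_line")
}

roi_in_bounds <- function(x, y, w, h, width, height) {
  x >= 0 && y >= 0 && (x + w) <= width && (y + h) <= height
}

#' Place standardized mesial and distal ROIs
#'
#' Finds, for each side, the admissible 10x30 rectangle closest to its anchor
#' point. For an implant the anchors sit at the first thread crest on either
#' side of the silhouette (mesial = lower-column side by convention); for a
#' [cej_line()] they are its two endpoints. A placement is admissible when the
#' rectangle lies fully inside the image and clears the exclusion mask
#' (implant threads, adjacent teeth, lamina dura, periodontal ligament,
#' alveolar crest, root surfaces) by at least one pixel. Distance is measured
#' from the rectangle's inner-edge midpoint (the edge facing the anchor) for
#' implants and from the rectangle centre for CEJ anchors; ties are broken
#' toward the alveolar crest (smaller row), then smaller column. The search is
#' exhaustive over the window, so the result is deterministic and
#' distance-minimal.
#'
#' @param image A [radiograph()].
#' @param anchor An [implant_geometry()] or [cej_line()]; defaults to the
#'   image's `"implant"` attribute.
#' @param exclusion Logical matrix, same size as `image`, of pixels an ROI may
#'   not touch. Defaults to the implant silhouette when the anchor is an
#'   implant, otherwise empty.
#' @param width,height ROI size in pixels.
#' @param search_radius Maximum anchor-to-ROI distance considered, pixels.
#'
#' @return A list with elements `mesial` and `distal` ([roi_spec()] or `NULL`
#'   when no admissible placement exists on that side) and attribute
#'   `"problems"`, a character vector naming the violated constraints per
#'   failed side. An error is thrown only if both sides fail.
#' @export
place_rois <- function(image, anchor = attr(image, "implant"), exclusion = NULL,
                       width = 10, height = 30, search_radius = 40) {
  stopifnot(inherits(image, "radiograph"))
  if (is.null(anchor)) stop("no anchor geometry supplied", call. = FALSE)
  W <- ncol(image)
  H <- nrow(image)
  if (is.null(exclusion)) {
    exclusion <- if (inherits(anchor, "implant_geometry")) {
      implant_mask(anchor, W, H)
    } else {
      matrix(FALSE, H, W)
    }
  }
  stopifnot(all(dim(exclusion) == dim(image)))
  # one-pixel clearance: forbid the exclusion mask grown by one pixel
  forbidden <- binary_dilate(exclusion)
  anchor_kind <- if (inherits(anchor, "implant_geometry")) "implant_first_thread" else "cej_line"
  if (anchor_kind == "implant_first_thread") {
    axis_col <- if (is.null(anchor$axis_col)) floor(W / 2) else anchor$axis_col
    maxhw <- anchor$radius + anchor$thread_amp
    pts <- list(
      mesial = c(axis_col - maxhw, anchor$first_thread_row),
      distal = c(axis_col + maxhw, anchor$first_thread_row)
    )
  } else {
    pts <- list(mesial = anchor$mesial, distal = anchor$distal)
  }
  pt_inside <- vapply(
    pts, function(p) p[1] >= 0 && p[1] <= W - 1 && p[2] >= 0 && p[2] <= H - 1,
    logical(1)
  )
  if (!any(pt_inside)) stop("anchor geometry lies outside the image", call. = FALSE)
  # column sums over sliding windows let us test mask overlap for every
  # candidate rectangle at once
  csum <- rect_window_sums(forbidden, width, height)
  out <- list(mesial = NULL, distal = NULL)
  problems <- character()
  for (side in c("mesial", "distal")) {
    if (!pt_inside[[side]]) {
      problems <- c(problems, sprintf("%s: anchor point lies outside the image", side))
      next
    }
    ap <- pts[[side]]
    xs <- seq.int(
      max(0, floor(ap[1] - search_radius - width)),
      min(W - width, ceiling(ap[1] + search_radius))
    )
    ys <- seq.int(
      max(0, floor(ap[2] - search_radius - height)),
      min(H - height, ceiling(ap[2] + search_radius))
    )
    if (length(xs) == 0 || length(ys) == 0 || xs[1] > utils::tail(xs, 1) ||
      ys[1] > utils::tail(ys, 1)) {
      problems <- c(problems, sprintf("%s: ROI does not fit inside the image", side))
      next
    }
    grid <- expand.grid(x = xs, y = ys)
    # reference point of each candidate: inner-edge midpoint (implant) or centre
    ref_x <- if (anchor_kind == "implant_first_thread") {
      if (side == "mesial") grid$x + width else grid$x
    } else {
      grid$x + width / 2
    }
    ref_y <- grid$y + height / 2
    d2 <- (ref_x - ap[1])^2 + (ref_y - ap[2])^2
    clear <- csum[cbind(grid$y + 1, grid$x + 1)] == 0
    ok <- clear & d2 <= search_radius^2
    if (!any(ok)) {
      problems <- c(problems, sprintf(
        "%s: no admissible %dx%d placement within %g px of the anchor (exclusion mask and bounds)",
        side, width, height, search_radius
      ))
      next
    }
    cand <- grid[ok, ]
    dd <- d2[ok]
    # min distance; ties toward the crest (smaller y), then smaller x
    ord <- order(dd, cand$y, cand$x)
    best <- cand[ord[1], ]
    out[[side]] <- roi_spec(best$x, best$y, width, height,
      side = side, anchor = anchor_kind
    )
  }
  if (is.null(out$mesial) && is.null(out$distal)) {
    stop(
      "no admissible ROI placement on either side:\n  ",
      paste(problems, collapse = "\n  "),
      call. = FALSE
    )
  }
  attr(out, "problems") <- problems
  out
}

# Number of TRUE pixels inside each w x h rectangle whose top-left (1-based)
# is (i, j); returned as an (H - h + 1) x (W - w + 1) matrix.
rect_window_sums <- function(mask, w, h) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  cs <- apply(m, 2, cumsum)
  cs <- rbind(0, cs)
  v <- cs[(h + 1):nrow(cs), , drop = FALSE] - cs[1:(nrow(cs) - h), , drop = FALSE]
  cs2 <- t(apply(v, 1, cumsum))
  cs2 <- cbind(0, cs2)
  cs2[, (w + 1):ncol(cs2), drop = FALSE] - cs2[, 1:(ncol(cs2) - w), drop = FALSE]
}

#' Extract an ROI patch
#'
#' Pixel-exact copy of the window defined by a [roi_spec()]; no interpolation
#' (images are aligned upstream by [register_rigid()] / [resample()]).
#'
#' @param image A [radiograph()].
#' @param spec A [roi_spec()], fully inside the image.
#' @return An object of class `roi_patch`: the pixel block with the spec and
#'   the source visit metadata attached.
#' @export
extract_roi <- function(image, spec) {
  stopifnot(inherits(image, "radiograph"), inherits(spec, "roi_spec"))
  if (!roi_in_bounds(spec$x, spec$y, spec$width, spec$height, ncol(image), nrow(image))) {
    stop("ROI spec lies outside the image bounds", call. = FALSE)
  }
  px <- unclass(image)[spec$y + seq_len(spec$height), spec$x + seq_len(spec$width), drop = FALSE]
  structure(px,
    class = c("roi_patch", "matrix", "array"),
    spec = spec, meta = radiograph_meta(image)
  )
}

#' Serialize ROI specs to a tibble
#'
#' @param specs A named list of [roi_spec()]s (as returned by [place_rois()]),
#'   `NULL` entries dropped.
#' @param patient_id Optional patient identifier column.
#' @return A tibble with one row per spec.
#' @export
roi_spec_table <- function(specs, patient_id = NA_character_) {
  specs <- purrr::compact(specs)
  purrr::map_dfr(specs, function(s) {
    tibble::tibble(
      patient_id = patient_id, side = s$side, x = s$x, y = s$y,
      width = s$width, height = s$height, anchor = s$anchor
    )
  })
}
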