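# -- binary morphology primitives (3x3 square structuring element) ----------
# Pixels outside the image count as background for both erosion and dilation.

pad_with <- function(m, value) {
  out <- matrix(value, nrow(m) + 2, ncol(m) + 2)
  out[2:(nrow(m) + 1), 2:(ncol(m) + 1)] <- m
  out
}

pad_false <- function(m) pad_with(m, FALSE)

neighborhood_sum3 <- function(m, pad = FALSE) {
  p <- pad_with(m, pad)
  h <- nrow(m)
  w <- ncol(m)
  acc <- matrix(0L, h, w)
  for (dr in 0:2) {
    for (dc in 0:2) {
      acc <- acc + p[dr + seq_len(h), dc + seq_len(w)]
    }
  }
  acc
}

#' Binary erosion and dilation (3x3 square)
#'
#' One iteration with the 3x3 square structuring element, the classical
#' binary denoising pair. Border handling is asymmetric by design: erosion
#' pads beyond the patch border with foreground (the border itself is not
#' evidence of marrow, so windowing must not eat the trabecular phase),
#' while dilation pads with background (nothing outside the window can seed
#' growth).
#'
#' @param mask Logical matrix.
#' @return Logical matrix of the same size.
#' @export
binary_erode <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  neighborhood_sum3(mask, pad = TRUE) == 9L
}

#' @rdname binary_erode
#' @export
binary_dilate <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  neighborhood_sum3(mask, pad = FALSE) >= 1L
}

# -- Gaussian blur with symmetric (half-sample reflection) border ------------

# Half-sample symmetric index: ... 2 1 | 1 2 ... n | n n-1 ...
reflect_index <- function(i, n) {
  j <- (i - 1) %% (2 * n)
  ifelse(j < n, j + 1, 2 * n - j)
}

gaussian_kernel_1d <- function(size, sigma) {
  stopifnot(size >= 1, size %% 2 == 1, sigma > 0)
  i <- seq.int(-(size - 1) / 2, (size - 1) / 2)
  w <- exp(-i^2 / (2 * sigma^2))
  w / sum(w)
}

conv_sym_cols <- function(m, w) {
  k <- (length(w) - 1) / 2
  n <- nrow(m)
  idx <- reflect_index(seq.int(1 - k, n + k), n)
  p <- m[idx, , drop = FALSE]
  out <- matrix(0, n, ncol(m))
  for (t in seq_along(w)) {
    out <- out + w[t] * p[(t - 1) + seq_len(n), , drop = FALSE]
  }
  out
}

#' Gaussian blur of an ROI patch
#'
#' Separable Gaussian smoothing used to remove fine and medium brightness
#' variation before background subtraction. The default kernel size is 35
#' pixels with `sigma = 35/6` (the convention that a discrete Gaussian's
#' effective support is +/- 3 sigma); sigma is exposed because historical
#' ImageJ reimplementations of this chain disagree on the parameterization.
#' The border is handled by half-sample reflection, which conserves total
#' intensity, and the result is kept at full floating-point precision for the
#' subtraction step.
#'
#' @param patch Numeric matrix (an [extract_roi()] patch or any gray image).
#' @param kernel_size Odd kernel width in pixels.
#' @param sigma Gaussian SD in pixels.
#' @return Numeric matrix, same size, full precision.
#' @export
pp_blur <- function(patch, kernel_size = 35, sigma = kernel_size / 6) {
  stopifnot(is.matrix(patch), is.numeric(patch), nrow(patch) >= 1, ncol(patch) >= 1)
  w <- gaussian_kernel_1d(kernel_size, sigma)
  t(conv_sym_cols(t(conv_sym_cols(unclass(patch) * 1.0, w)), w))
}

#' Background subtraction with mid-gray offset
#'
#' `original - blurred + 128`, kept in floating point. Because the blur is
#' linear and intensity-conserving, adding a constant to the input shifts
#' both terms equally, so the output -- and everything downstream -- is
#' invariant to global brightness changes (e.g. exposure differences between
#' visits).
#'
#' @param original,blurred Numeric matrices of identical size.
#' @return Numeric matrix centred near 128.
#' @export
pp_subtract_offset <- function(original, blurred) {
  if (!all(dim(original) == dim(blurred))) {
    stop("`original` and `blurred` must have identical dimensions", call. = FALSE)
  }
  unclass(original) * 1.0 - blurred + 128
}

#' Binarize at the mid-gray threshold
#'
#' Foreground (trabecular bone, the locally bright phase) is every pixel with
#' value `>= threshold - tol`. The tolerance (default 1e-6 gray levels)
#' guards exact-mean plateaus: a perfectly flat field lands at 128 up to
#' floating-point roundoff and must binarize as foreground, while values
#' meaningfully below 128 (e.g. 127.9) stay background.
#'
#' @param x Numeric matrix (the offset difference image).
#' @param threshold Gray-level threshold.
#' @param tol Numerical tolerance below the threshold still accepted.
#' @return Logical matrix.
#' @export
pp_binarize <- function(x, threshold = 128, tol = 1e-6) {
  stopifnot(is.matrix(x), is.numeric(x))
  unclass(x) >= (threshold - tol)
}

#' Morphological opening for speckle removal
#'
#' One erosion followed by one dilation with the 3x3 square element; removes
#' isolated single-pixel noise while leaving large blobs unchanged.
#'
#' @param mask Logical matrix.
#' @return Logical matrix.
#' @export
pp_open <- function(mask) {
  binary_dilate(binary_erode(mask))
}

#' Outline a binary mask
#'
#' Keeps foreground pixels that touch the background through at least one
#' 4-neighbour (pixels beyond the border count as background, so foreground
#' on the patch border is always outline).
#'
#' @param mask Logical matrix.
#' @return Logical matrix.
#' @export
pp_outline <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  p <- pad_false(mask)
  h <- nrow(mask)
  w <- ncol(mask)
  bg4 <- (!p[seq_len(h), 1 + seq_len(w)]) + (!p[2 + seq_len(h), 1 + seq_len(w)]) +
    (!p[1 + seq_len(h), seq_len(w)]) + (!p[1 + seq_len(h), 2 + seq_len(w)])
  mask & bg4 >= 1
}

#' Zhang-Suen topological thinning
#'
#' Iteratively peels a binary mask down to one-pixel-wide, 8-connected
#' centrelines using the two-subiteration Zhang-Suen rules; already-thin
#' structures (1-px lines) pass through unchanged.
#'
#' @param mask Logical matrix.
#' @return Logical matrix (the skeleton).
#' @export
pp_skeletonize <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  m <- mask
  h <- nrow(m)
  w <- ncol(m)
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      p <- pad_false(m)
      N <- p[seq_len(h), 1 + seq_len(w)]
      S <- p[2 + seq_len(h), 1 + seq_len(w)]
      W_ <- p[1 + seq_len(h), seq_len(w)]
      E <- p[1 + seq_len(h), 2 + seq_len(w)]
      NE <- p[seq_len(h), 2 + seq_len(w)]
      SE <- p[2 + seq_len(h), 2 + seq_len(w)]
      SW <- p[2 + seq_len(h), seq_len(w)]
      NW <- p[seq_len(h), seq_len(w)]
      B <- N + NE + E + SE + S + SW + W_ + NW
      seq9 <- list(N, NE, E, SE, S, SW, W_, NW, N)
      A <- matrix(0L, h, w)
      for (i in 1:8) A <- A + (!seq9[[i]] & seq9[[i + 1]])
      cond <- m & B >= 2 & B <= 6 & A == 1
      if (sub == 1) {
        cond <- cond & !(N & E & S) & !(E & S & W_)
      } else {
        cond <- cond & !(N & E & W_) & !(N & S & W_)
      }
      if (any(cond)) {
        m[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

CHAIN_STEPS <- c(
  "blur", "subtract", "add128", "threshold",
  "erode", "dilate", "outline", "skeletonize"
)

#' Run the full trabecular preprocessing chain
#'
#' Transforms a gray-level ROI patch into the binary skeletonized trabecular
#' pattern that feeds box counting: Gaussian blur (background estimate),
#' subtract + 128 offset, threshold at 128, morphological opening (one
#' erosion, one dilation), outline, Zhang-Suen skeletonization. Intermediate
#' stages are computed in floating point; the only quantization is the
#' binarization itself. The chain is deterministic and invariant to global
#' brightness shifts of the input (up to gray-level saturation).
#'
#' @param patch Numeric matrix or [extract_roi()] patch.
#' @param kernel_size,sigma Blur parameters, see [pp_blur()].
#' @param threshold Binarization threshold, see [pp_binarize()].
#' @param keep_stages If `TRUE`, all intermediate images are attached as
#'   attribute `"stages"` (for a contact-sheet figure).
#' @return A [skeleton_mask()] whose provenance lists the eight applied steps
#'   in canonical order.
#' @export
#' @examples
#' patch <- matrix(rep(c(120, 136), 150), 30, 10)
#' sk <- run_chain(patch)
#' sum(sk)
run_chain <- function(patch, kernel_size = 35, sigma = kernel_size / 6,
                      threshold = 128, keep_stages = FALSE) {
  px <- unclass(patch) * 1.0
  stopifnot(is.matrix(px), is.numeric(px))
  blurred <- pp_blur(px, kernel_size, sigma)
  offset <- pp_subtract_offset(px, blurred)
  bin <- pp_binarize(offset, threshold)
  opened <- pp_open(bin)
  outline <- pp_outline(opened)
  skel <- pp_skeletonize(outline)
  out <- skeleton_mask(skel,
    provenance = CHAIN_STEPS,
    params = list(kernel_size = kernel_size, sigma = sigma, threshold = threshold)
  )
  attr(out, "meta") <- attr(patch, "meta")
  attr(out, "spec") <- attr(patch, "spec")
  if (keep_stages) {
    attr(out, "stages") <- list(
      original = px, blurred = blurred, offset = offset,
      binary = bin, opened = opened, outline = outline, skeleton = skel
    )
  }
  out
}

#' Check skeleton thinness
#'
#' A skeleton is thin when it contains no 2x2 all-foreground block.
#'
#' @param mask Logical matrix or [skeleton_mask()].
#' @return `TRUE`/`FALSE`.
#' @export
skeleton_is_thin <- function(mask) {
  m <- unclass(mask)
  if (nrow(m) < 2 || ncol(m) < 2) {
    return(TRUE)
  }
  blk <- m[-nrow(m), -ncol(m)] & m[-1, -ncol(m)] & m[-nrow(m), -1] & m[-1, -1]
  !any(blk)
}
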