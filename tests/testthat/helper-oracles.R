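# Independent brute-force oracles used to validate the fast implementations.

# Direct 2-D Gaussian convolution with half-sample symmetric reflection,
# written as explicit loops over the full 2-D kernel (no separability).
oracle_blur <- function(patch, kernel_size = 35, sigma = kernel_size / 6) {
  k <- (kernel_size - 1) / 2
  i <- seq.int(-k, k)
  w1 <- exp(-i^2 / (2 * sigma^2))
  w1 <- w1 / sum(w1)
  w2 <- outer(w1, w1)
  h <- nrow(patch)
  wd <- ncol(patch)
  refl <- function(i, n) {
    j <- (i - 1) %% (2 * n)
    ifelse(j < n, j + 1, 2 * n - j)
  }
  out <- matrix(0, h, wd)
  for (r in seq_len(h)) {
    for (c in seq_len(wd)) {
      rr <- refl(r + i, h)
      cc <- refl(c + i, wd)
      out[r, c] <- sum(w2 * patch[rr, cc])
    }
  }
  out
}

# Set-arithmetic binary morphology with explicit neighbourhood scans.
# Erosion treats out-of-image as foreground, dilation as background,
# matching the documented border convention.
oracle_erode <- function(mask) {
  h <- nrow(mask)
  w <- ncol(mask)
  out <- matrix(FALSE, h, w)
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      keep <- TRUE
      for (dr in -1:1) {
        for (dc in -1:1) {
          rr <- r + dr
          cc <- c + dc
          inside <- rr >= 1 && rr <= h && cc >= 1 && cc <= w
          if (inside && !mask[rr, cc]) keep <- FALSE
        }
      }
      out[r, c] <- mask[r, c] && keep
    }
  }
  out
}

oracle_dilate <- function(mask) {
  h <- nrow(mask)
  w <- ncol(mask)
  out <- matrix(FALSE, h, w)
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      hit <- FALSE
      for (dr in -1:1) {
        for (dc in -1:1) {
          rr <- r + dr
          cc <- c + dc
          if (rr >= 1 && rr <= h && cc >= 1 && cc <= w && mask[rr, cc]) hit <- TRUE
        }
      }
      out[r, c] <- hit
    }
  }
  out
}

# Occupied-box counts by direct tile scan (no index arithmetic shared with
# the implementation).
oracle_box_counts <- function(mask, sizes) {
  vapply(sizes, function(s) {
    n <- 0L
    for (r0 in seq(1, nrow(mask), by = s)) {
      for (c0 in seq(1, ncol(mask), by = s)) {
        blk <- mask[r0:min(r0 + s - 1, nrow(mask)), c0:min(c0 + s - 1, ncol(mask)), drop = FALSE]
        if (any(blk)) n <- n + 1L
      }
    }
    n
  }, integer(1))
}

# Recursive construction of Sierpinski carpet occupancy: number of occupied
# 3^k-sized boxes of the level-L carpet is 8^(L - k).
oracle_carpet_boxes <- function(level, k) 8^(level - k)

# Brute-force ROI search: scan every in-bounds top-left position, keep those
# clearing the grown exclusion mask, return the minimal distance achieved.
oracle_roi_min_dist <- function(anchor_xy, forbidden, w = 10, h = 30,
                                ref = c("inner_right", "inner_left")) {
  ref <- match.arg(ref)
  W <- ncol(forbidden)
  H <- nrow(forbidden)
  best <- Inf
  for (x in 0:(W - w)) {
    for (y in 0:(H - h)) {
      blk <- forbidden[y + seq_len(h), x + seq_len(w), drop = FALSE]
      if (any(blk)) next
      rx <- if (ref == "inner_right") x + w else x
      d <- sqrt((rx - anchor_xy[1])^2 + (y + h / 2 - anchor_xy[2])^2)
      best <- min(best, d)
    }
  }
  best
}

# One standard small phantom per seed for property loops.
test_phantom <- function(seed, hurst = 0.5, ...) {
  trabecular_phantom(hurst = hurst, seed = seed, ...)
}

# FD of one phantom through ROI placement, preprocessing and box counting,
# averaged over the mesial and distal sides.
pipeline_fd <- function(image) {
  rois <- place_rois(image)
  mean(c(
    box_count(run_chain(extract_roi(image, rois$mesial)))$fd,
    box_count(run_chain(extract_roi(image, rois$distal)))$fd
  ))
}
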