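test_that("Gaussian blur matches a direct 2-D convolution oracle", {
  set.seed(1)
  patch <- matrix(runif(300, 0, 255), 30, 10)
  expect_equal(pp_blur(patch), oracle_blur(patch), tolerance = 1e-10)
  # constant input is preserved
  flat <- matrix(55, 30, 10)
  expect_equal(pp_blur(flat), flat, tolerance = 1e-9)
  # reflection border conserves total mass (single bright pixel)
  imp <- matrix(0, 40, 40)
  imp[17, 23] <- 1000
  expect_equal(sum(pp_blur(imp)), 1000, tolerance = 1e-6)
  # a period-2 checkerboard is flattened to its mean
  chk <- 100 + 20 * outer(1:30, 1:10, function(r, c) (r + c) %% 2)
  bl <- pp_blur(chk)
  expect_lt(max(abs(bl - mean(chk))), 1.5)
})

test_that("background subtraction centres at 128 and shifts cancel", {
  flat <- matrix(90, 30, 10)
  expect_equal(pp_subtract_offset(flat, pp_blur(flat)), matrix(128, 30, 10))
  expect_equal(
    pp_subtract_offset(flat + 10, flat),
    matrix(138, 30, 10)
  )
  expect_error(pp_subtract_offset(flat, matrix(0, 5, 5)), "dimensions")
})

test_that("binarization side convention is explicit at the 128 threshold", {
  expect_true(all(pp_binarize(matrix(128, 5, 5))))
  expect_false(any(pp_binarize(matrix(127.9, 5, 5))))
  stripes <- matrix(rep(c(120, 136), length.out = 300), 30, 10)
  expect_equal(pp_binarize(stripes), stripes >= 128)
})

test_that("morphological opening matches the set-arithmetic oracle", {
  set.seed(2)
  for (i in 1:5) {
    speck <- matrix(runif(300) < 0.35, 30, 10)
    expect_identical(binary_erode(speck), oracle_erode(speck))
    expect_identical(binary_dilate(speck), oracle_dilate(speck))
    expect_identical(pp_open(speck), oracle_dilate(oracle_erode(speck)))
  }
  # opening removes isolated pixels but keeps solid blobs
  single <- matrix(FALSE, 9, 9)
  single[5, 5] <- TRUE
  expect_false(any(pp_open(single)))
  sq <- matrix(FALSE, 11, 11)
  sq[4:8, 4:8] <- TRUE
  expect_identical(pp_open(sq), sq)
})

test_that("outline extracts boundary pixels, skeletonization thins to 1 px", {
  expect_false(any(pp_outline(matrix(FALSE, 10, 10))))
  # solid disc: outline is a 1-px ring whose skeleton stays a closed curve
  rr <- outer(-10:10, -10:10, function(r, c) sqrt(r^2 + c^2))
  disc <- rr <= 8
  ring <- pp_outline(disc)
  expect_true(all(ring[disc & rr > 7.3]))
  expect_false(any(ring[rr <= 6.5]))
  sk <- pp_skeletonize(ring)
  expect_true(skeleton_is_thin(sk))
  # closed curve: every skeleton pixel keeps at least two 8-neighbours
  idx <- which(sk, arr.ind = TRUE)
  nb <- vapply(seq_len(nrow(idx)), function(i) {
    r <- idx[i, 1]
    c <- idx[i, 2]
    sum(sk[max(1, r - 1):min(nrow(sk), r + 1), max(1, c - 1):min(ncol(sk), c + 1)]) - 1L
  }, integer(1))
  expect_true(all(nb >= 2))
  # a 1-px line passes through unchanged
  line <- matrix(FALSE, 15, 15)
  line[8, 3:13] <- TRUE
  expect_identical(pp_skeletonize(line), line)
  # thick bar thins to a single-pixel-wide centreline
  bar <- matrix(FALSE, 15, 15)
  bar[6:10, 2:14] <- TRUE
  thin <- pp_skeletonize(bar)
  expect_true(skeleton_is_thin(thin))
  expect_gt(sum(thin), 0)
})

test_that("the full chain records provenance and handles a constant patch", {
  flat <- matrix(100, 30, 10)
  sk <- run_chain(flat)
  expect_s3_class(sk, "skeleton_mask")
  expect_identical(
    attr(sk, "provenance"),
    c("blur", "subtract", "add128", "threshold", "erode", "dilate", "outline", "skeletonize")
  )
  # constant -> uniform 128 -> all foreground -> outline is the border frame
  frame <- matrix(FALSE, 30, 10)
  frame[c(1, 30), ] <- TRUE
  frame[, c(1, 10)] <- TRUE
  expect_identical(unclass(sk)[, ], frame)
  # the frame's box counts follow the closed form for boundary tiles
  b <- box_count(sk)
  expected <- vapply(b$tile_sizes, function(s) {
    nr <- ceiling(30 / s)
    nc <- ceiling(10 / s)
    if (nr <= 2 || nc <= 2) nr * nc else 2 * (nr + nc) - 4
  }, numeric(1))
  expect_equal(b$counts, as.integer(expected))
})

test_that("the chain is bit-invariant to global brightness shifts", {
  for (seed in 1:6) {
    ph <- trabecular_phantom(mean_gray = 128, contrast = 18, seed = seed)
    patch <- extract_roi(ph, place_rois(ph)$mesial)
    base <- run_chain(patch)
    for (c0 in c(-20, -3, 8, 20)) {
      shifted <- unclass(patch) + c0
      expect_identical(unclass(run_chain(shifted))[, ], unclass(base)[, ])
    }
  }
})

test_that("skeletons from the chain are always strictly thin", {
  for (seed in 1:8) {
    ph <- test_phantom(seed, hurst = runif(1, 0.15, 0.85))
    sk <- run_chain(extract_roi(ph, place_rois(ph)$mesial))
    expect_true(skeleton_is_thin(sk))
    expect_type(unclass(sk)[, ], "logical")
  }
})

test_that("higher texture complexity yields more skeleton pixels", {
  px_complex <- vapply(1:12, function(s) {
    ph <- trabecular_phantom(hurst = 0.2, seed = s)
    sum(run_chain(extract_roi(ph, place_rois(ph)$mesial)))
  }, numeric(1))
  px_smooth <- vapply(1:12, function(s) {
    ph <- trabecular_phantom(hurst = 0.8, seed = s)
    sum(run_chain(extract_roi(ph, place_rois(ph)$mesial)))
  }, numeric(1))
  expect_gt(median(px_complex), median(px_smooth))
})
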