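test_that("ROIs abut the implant symmetrically at the first-thread row", {
  geom <- implant_geometry(radius = 12, thread_pitch = 8, top_row = 30)
  ph <- trabecular_phantom(implant = geom, seed = 2)
  rois <- place_rois(ph)
  m <- rois$mesial
  d <- rois$distal
  expect_equal(m$width, 10)
  expect_equal(m$height, 30)
  axis_col <- floor(ncol(ph) / 2)
  # symmetric about the implant axis (inner edges equidistant)
  expect_equal(axis_col - (m$x + m$width - 1), d$x - axis_col)
  expect_equal(m$y, d$y)
  # vertically centred on the first-thread row (tie broken toward the crest)
  expect_true(abs(m$y + m$height / 2 - geom$first_thread_row) <= 1)
  # one-pixel clearance from the silhouette
  mask <- implant_mask(geom, ncol(ph), nrow(ph))
  grown <- binary_dilate(mask)
  blk <- grown[m$y + seq_len(m$height), m$x + seq_len(m$width)]
  expect_false(any(blk))
})

test_that("placement is deterministic and distance-minimal under an exclusion mask", {
  geom <- implant_geometry(radius = 12, thread_pitch = 8, top_row = 30)
  ph <- trabecular_phantom(implant = geom, seed = 2)
  W <- ncol(ph)
  H <- nrow(ph)
  axis_col <- floor(W / 2)
  excl <- implant_mask(geom, W, H)
  # block the naturally abutting mesial position
  free <- place_rois(ph)
  fx <- free$mesial$x
  fy <- free$mesial$y
  excl[fy + seq_len(30), fx + seq_len(10)] <- TRUE

  rois <- place_rois(ph, anchor = geom, exclusion = excl)
  expect_identical(rois, place_rois(ph, anchor = geom, exclusion = excl))
  m <- rois$mesial
  # brute-force scan confirms minimality of the achieved distance
  anchor_xy <- c(axis_col - (geom$radius + geom$thread_amp), geom$first_thread_row)
  forbidden <- binary_dilate(excl)
  best <- oracle_roi_min_dist(anchor_xy, forbidden, ref = "inner_right")
  got <- sqrt((m$x + m$width - anchor_xy[1])^2 + (m$y + m$height / 2 - anchor_xy[2])^2)
  expect_equal(got, best, tolerance = 1e-9)
  # and the blocked rectangle was indeed avoided
  blk <- forbidden[m$y + seq_len(30), m$x + seq_len(10)]
  expect_false(any(blk))
})

test_that("an implant close to the image edge fails one side but returns the other", {
  geom <- implant_geometry(axis_col = 6, radius = 5, thread_pitch = 8, top_row = 30)
  ph <- trabecular_phantom(implant = geom, seed = 2)
  rois <- place_rois(ph, anchor = geom)
  expect_null(rois$mesial)
  expect_s3_class(rois$distal, "roi_spec")
  expect_match(paste(attr(rois, "problems"), collapse = " "), "mesial")
})

test_that("no admissible placement on either side raises a placement error", {
  geom <- implant_geometry(radius = 12)
  ph <- trabecular_phantom(implant = geom, seed = 2)
  excl <- matrix(TRUE, nrow(ph), ncol(ph))
  expect_error(place_rois(ph, anchor = geom, exclusion = excl), "no admissible")
})

test_that("CEJ-anchored control ROIs sit near the reference line endpoints", {
  ph <- trabecular_phantom(seed = 4, implant = NULL)
  line <- cej_line(mesial = c(40, 60), distal = c(120, 60))
  rois <- place_rois(ph, anchor = line)
  expect_equal(rois$mesial$anchor, "cej_line")
  expect_lt(abs(rois$mesial$x + 5 - 40), 2)
  expect_lt(abs(rois$distal$x + 5 - 120), 2)
})

test_that("extraction is pixel-exact and translation-equivariant", {
  ph <- trabecular_phantom(seed = 9, implant = NULL)
  spec <- roi_spec(30, 40, side = "mesial")
  patch <- extract_roi(ph, spec)
  expect_equal(dim(patch), c(30, 10))
  expect_equal(
    unclass(patch)[, ],
    unclass(ph)[41:70, 31:40],
    ignore_attr = TRUE
  )
  # constant region -> single unique value
  flat <- radiograph(matrix(42, 120, 120))
  expect_equal(unique(as.vector(extract_roi(flat, spec))), 42)
  # identical copies give identical patches
  expect_identical(
    unclass(extract_roi(ph, spec)),
    unclass(extract_roi(ph, spec))
  )
  # integer-shifted image with shifted spec gives the identical patch
  sh <- resample(ph, rigid_transform(7, 4, 0))
  spec2 <- roi_spec(30 + 7, 40 + 4, side = "mesial")
  expect_equal(
    unclass(extract_roi(sh, spec2))[, ],
    unclass(extract_roi(ph, spec))[, ],
    ignore_attr = TRUE
  )
  expect_error(extract_roi(ph, roi_spec(155, 40)), "bounds")
})

test_that("roi specs serialize to a tidy table", {
  ph <- trabecular_phantom(seed = 2)
  tab <- roi_spec_table(place_rois(ph), patient_id = "P01")
  expect_equal(nrow(tab), 2)
  expect_setequal(tab$side, c("mesial", "distal"))
  expect_true(all(tab$width == 10 & tab$height == 30))
})
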