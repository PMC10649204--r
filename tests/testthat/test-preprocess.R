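test_that("detect_marker finds a synthetic disc to subpixel accuracy", {
  set.seed(1)
  nr <- 200; nc <- 200
  plane <- matrix(0.6, nr, nc) + matrix(rnorm(nr * nc, 0, 0.005), nr, nc)
  ctr <- c(71.0, 123.0)
  Rm <- matrix(seq_len(nr), nr, nc); Cm <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  disc <- (Rm - ctr[1])^2 + (Cm - ctr[2])^2 <= 14^2
  plane[disc] <- 0.02
  det <- detect_marker(plane, darkness_quantile = 0.02)
  expect_lt(max(abs(det$centroid - ctr)), 0.5)
  expect_true(all(det$mask[disc] | !disc[det$mask]))
})

test_that("detect_marker rejects degenerate and ambiguous inputs", {
  # uniform image: the dark component spans everything -> rejected
  expect_error(detect_marker(matrix(0.5, 100, 100)),
               class = "nf_marker_not_found")

  # two dark blobs, one 3x larger: centroid of the larger one
  plane <- matrix(0.6, 150, 150)
  Rm <- matrix(seq_len(150), 150, 150)
  Cm <- matrix(seq_len(150), 150, 150, byrow = TRUE)
  small <- (Rm - 40)^2 + (Cm - 40)^2 <= 6^2
  big <- (Rm - 100)^2 + (Cm - 110)^2 <= (6 * sqrt(3))^2
  expect_gt(sum(big), 3 * sum(small) * 0.9)
  plane[small] <- 0.02; plane[big] <- 0.02
  det <- detect_marker(plane, darkness_quantile = 0.02)
  expect_lt(max(abs(det$centroid - c(100, 110))), 1)
})

test_that("stabilize recovers generator offsets within 1 px per axis", {
  offs <- list(AF405 = c(4, -2), G526 = c(0, 0), R663 = c(3, -2),
               IR964 = c(-5, 5))
  sc <- make_scene(seed = 42, size = c(384, 384), offsets = offs)
  mset <- multispectral_set(sc$images, "t")
  al <- stabilize(mset)
  shifts <- attr(al, "shifts")
  for (b in spectral_bands()) {
    expect_lte(max(abs(shifts[[b]] - offs[[b]])), 1)
  }
  # post-stabilization marker centroids agree pairwise within 1 px
  cents <- vapply(al$planes, function(p) detect_marker(p)$centroid, numeric(2))
  expect_lt(max(cents[1, ]) - min(cents[1, ]), 1)
  expect_lt(max(cents[2, ]) - min(cents[2, ]), 1)
})

test_that("stabilize with zero offsets is the identity (no crop)", {
  sc <- make_scene(seed = 17, offsets = zero_offsets(), noise_sd = 0)
  mset <- multispectral_set(sc$images, "t")
  al <- stabilize(mset)
  expect_identical(dim(al$planes$G526), dim(mset$planes$G526))
  expect_equal(al$planes$G526, mset$planes$G526, ignore_attr = TRUE)
  expect_true(al$aligned)
})

test_that("estimate_skin_range matches mean +/- k SD and widens degenerate input", {
  # constant annulus -> degenerate range widened by 0.01
  nr <- 120
  plane <- matrix(0.6, nr, nr)
  marker <- .disc_mask <- matrix(FALSE, nr, nr)
  Rm <- matrix(seq_len(nr), nr, nr); Cm <- t(Rm)
  marker <- (Rm - 60)^2 + (Cm - 60)^2 <= 10^2
  sr <- estimate_skin_range(plane, marker)
  expect_equal(sr$skin_range, c(0.59, 0.61))

  # Normal(0.6, 0.02) annulus, k = 2 -> approximately (0.56, 0.64)
  set.seed(3)
  plane2 <- matrix(rnorm(nr * nr, 0.6, 0.02), nr, nr)
  sr2 <- estimate_skin_range(plane2, marker, k = 2)
  expect_equal(sr2$skin_range[1], 0.56, tolerance = 0.01)
  expect_equal(sr2$skin_range[2], 0.64, tolerance = 0.01)
  # direct mean/SD oracle on the annulus pixels
  px <- plane2[sr2$skin_mask]
  expect_equal(sr2$skin_range, c(mean(px) - 2 * sd(px), mean(px) + 2 * sd(px)))
})

test_that("a marker placed too close to the lesion inflates the G annulus SD", {
  # adversarial scene: lesion edge inside the skin annulus of the marker
  set.seed(91)
  # AF target equals the AF skin base so only the G band is contaminated
  targets <- data.frame(af = 0.35, gmin5 = 0.35, pmin5 = -0.2)
  spec <- scene_spec(size = test_scene_size, marker_radius = 9,
                     marker_center = c(96, 60),
                     lesion_center = c(96, 102), lesion_axes = c(30, 26),
                     offsets = zero_offsets())
  sc <- render_scene(spec, targets)
  pl <- scene_planes(sc)
  det <- detect_marker(pl$G526)
  sds <- vapply(pl, function(p)
    estimate_skin_range(p, det$mask)$sd, numeric(1))
  # the lesion contaminates the annulus only in the contrast bands;
  # the G-band SD blows up relative to the across-band median
  expect_gt(sds[["G526"]], 3 * median(sds))

  # and a well-separated scene from the same generator does not flag
  sc_ok <- make_scene(seed = 91, offsets = zero_offsets())
  seg_ok <- segment_scene(stabilize(multispectral_set(sc_ok$images, "t")))
  expect_false(any(grepl("annulus_inflated", seg_ok$flags)))
})

test_that("segmentation is precise on clean scenes and errors when contrast vanishes", {
  sc <- make_clean_scene(seed = 55, neutral_r_ir = FALSE)
  res <- process_scene(sc$images)
  gt <- crop_to_window(sc$truth$lesion_mask, res$window)
  expect_gte(mask_iou(res$seg$lesion_mask, gt), 0.95)

  # masks partition: pairwise disjoint
  seg <- res$seg
  expect_false(any(seg$marker_mask & seg$skin_mask))
  expect_false(any(seg$marker_mask & seg$lesion_mask))
  expect_false(any(seg$skin_mask & seg$lesion_mask))

  # lesion intensity inside the skin range -> nothing below threshold
  pl <- scene_planes(sc)
  expect_error(
    segment_lesion(pl$G526, sc$truth$marker_mask,
                   skin_range = c(0.0, 0.2)),
    class = "nf_segmentation_failed")
})

test_that("segmentation IoU does not degrade when lesion contrast increases", {
  # same geometry/noise seed, decreasing lesion intensity (gmin5 target)
  ious <- vapply(c(0.45, 0.35, 0.25, 0.15), function(g) {
    targets <- data.frame(af = 0.25, gmin5 = g, pmin5 = -0.3)
    sc <- make_scene(seed = 500, targets = targets)
    res <- process_scene(sc$images)
    gt <- crop_to_window(sc$truth$lesion_mask, res$window)
    mask_iou(res$seg$lesion_mask, gt)
  }, numeric(1))
  expect_true(all(diff(ious) >= -0.02))
  expect_gt(min(ious), 0.8)
})

test_that("mask overrides replace the automatic segmentation", {
  sc <- make_scene(seed = 23, offsets = zero_offsets())
  auto <- process_scene(sc$images)

  # override identical to the auto mask -> identical downstream features
  same <- process_scene(sc$images, override_mask = auto$seg$lesion_mask)
  expect_equal(same$features$bands$G526$lesion$mean,
               auto$features$bands$G526$lesion$mean)
  expect_identical(same$seg$mask_source, "override")

  # override from file, with known pixel count flowing into n_pixels
  f <- withr::local_tempfile(fileext = ".png")
  hand <- matrix(FALSE, nrow(auto$seg$lesion_mask), ncol(auto$seg$lesion_mask))
  hand[40:60, 50:80] <- TRUE
  write_mask_png(hand, f)
  over <- process_scene(sc$images, override_mask = f)
  expect_equal(over$features$bands$G526$lesion$n_pixels, sum(hand))

  # all-zero mask is rejected
  f0 <- withr::local_tempfile(fileext = ".png")
  write_mask_png(hand & FALSE, f0)
  expect_error(process_scene(sc$images, override_mask = f0),
               class = "nf_format_error")
  # shape mismatch is rejected
  expect_error(load_mask_override(f, c(10, 10)), class = "nf_format_error")
})
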