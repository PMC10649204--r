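test_that("sample_lesion_targets draws from the calibrated Normals", {
  cal <- class_calibrations()
  cafe <- cal[cal$class_label == "cafe_au_lait", ]

  # degenerate sd -> targets equal the calibrated means
  d <- cafe; d$af_sd <- d$gmin5_sd <- d$pmin5_sd <- 0
  t0 <- sample_lesion_targets(d, 3)
  expect_equal(t0$af, rep(0.27, 3))
  expect_equal(t0$gmin5, rep(0.41, 3))
  expect_equal(t0$pmin5, rep(-0.16, 3))

  # determinism under a fixed seed
  set.seed(77); a <- sample_lesion_targets("cafe_au_lait", 5)
  set.seed(77); b <- sample_lesion_targets("cafe_au_lait", 5)
  expect_identical(a, b)

  # 10,000 draws: sample mean of gmin5 within 3 standard errors of 0.41
  set.seed(2024)
  t1 <- sample_lesion_targets(cafe, 10000)
  expect_lt(abs(mean(t1$gmin5) - 0.41), 3 * 0.07 / sqrt(10000))
  expect_lt(abs(mean(t1$af) - 0.27), 3 * 0.10 / sqrt(10000))
  # clamped to the physically valid ranges
  expect_true(all(t1$gmin5 > 0 & t1$gmin5 <= 1))
  expect_true(all(t1$af > 0 & t1$af <= 1))
  expect_true(all(t1$pmin5 < 0))
})

test_that("exact construction: pipeline-free statistics hit drawn targets", {
  for (cl in c("cafe_au_lait", "neurofibroma", "intradermal_nevus",
               "junctional_nevus")) {
    sc <- make_clean_scene(cl, seed = 31)
    pl <- scene_planes(sc)
    E <- sc$truth$lesion_mask
    got_af <- region_stats(pl$AF405, E)$mean
    got_g <- region_stats(pl$G526, E)$mean_min5
    expect_lt(abs(got_af - sc$truth$targets_achieved$af), 1e-9)
    expect_lt(abs(got_g - sc$truth$targets_achieved$gmin5), 1e-9)
    pm <- p_prime_map(pl$G526, pl$R663, pl$IR964, E,
                      c(G526 = sc$truth$skin_base[["G526"]],
                        R663 = sc$truth$skin_base[["R663"]],
                        IR964 = sc$truth$skin_base[["IR964"]]))
    k <- ceiling(0.05 * sum(E))
    got_p <- mean(sort(pm$values)[seq_len(k)])
    expect_lt(abs(got_p - sc$truth$targets_achieved$pmin5), 1e-6)
  }
})

test_that("marker pixels are the strict global minimum pre-noise", {
  sc <- make_clean_scene(seed = 8, neutral_r_ir = FALSE)
  for (b in spectral_bands()) {
    pl <- extract_channel(sc$images[[b]], b)
    inside <- pl[sc$truth$marker_mask]
    outside <- pl[!sc$truth$marker_mask]
    expect_lt(max(inside), min(outside))
  }
})

test_that("neutral-R/IR p-prime equals the G ratio term alone", {
  sc <- make_clean_scene(seed = 14, neutral_r_ir = TRUE)
  pl <- scene_planes(sc)
  E <- sc$truth$lesion_mask
  pm <- p_prime_map(pl$G526, pl$R663, pl$IR964, E,
                    c(G526 = sc$truth$skin_base[["G526"]],
                      R663 = sc$truth$skin_base[["R663"]],
                      IR964 = sc$truth$skin_base[["IR964"]]))
  expect_equal(pm$values,
               log10(pl$G526[E] / sc$truth$skin_base[["G526"]]),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("rendered offsets and masks are consistent with ground truth", {
  offs <- list(AF405 = c(2, -4), G526 = c(0, 0), R663 = c(-3, 5),
               IR964 = c(1, 1))
  sc <- make_scene(seed = 21, noise_sd = 0, offsets = offs)
  g_ref <- extract_channel(sc$images$G526, "G526")
  r_shift <- extract_channel(sc$images$R663, "R663")
  # shifting the R663 image back by its offset must reproduce the
  # reference-frame geometry where both are defined
  nr <- nrow(g_ref)
  rows <- 10:(nr - 10); cols <- 10:(ncol(g_ref) - 10)
  back <- r_shift[rows + offs$R663[1], cols + offs$R663[2]]
  ref_marker <- sc$truth$marker_mask[rows, cols]
  expect_true(all(back[ref_marker] == 0.02))
  expect_false(any(sc$truth$lesion_mask & sc$truth$marker_mask))
})

test_that("infeasible fixed skin base raises a calibration error", {
  set.seed(4)
  targets <- data.frame(af = 0.3, gmin5 = 0.5, pmin5 = -0.2)
  spec <- random_scene_spec(size = test_scene_size, axes_range = c(25, 35),
                            marker_radius = 14)
  expect_error(render_scene(spec, targets, fixed_skin_g = 0.4),
               class = "nf_calibration_error")
})

test_that("render_cohort reproduces the study cohort composition", {
  m <- render_cohort("nf1_2023", seed = 9)
  expect_equal(nrow(m), 256)
  expect_equal(sum(m$nf1_related), 90)
  expect_equal(sum(!m$nf1_related), 166)
  counts <- table(m$class_label)
  expect_equal(counts[["cafe_au_lait"]], 25)
  expect_equal(counts[["neurofibroma"]], 65)
  expect_equal(counts[["dermatofibroma"]], 16)
  expect_equal(counts[["intradermal_nevus"]], 4)
  expect_equal(counts[["junctional_nevus"]], 129)
  expect_equal(counts[["lentigo_solaris"]], 17)

  # custom preset with zero rows of a class
  m2 <- render_cohort("custom", seed = 9,
                      n_per_class = c(cafe_au_lait = 3, neurofibroma = 0))
  expect_equal(nrow(m2), 3)
  expect_true(all(m2$class_label == "cafe_au_lait"))
  expect_error(render_cohort("custom", seed = 9,
                             n_per_class = c(melanoma = 2)),
               class = "nf_format_error")
})

test_that("identical seeds give bit-identical scenes and manifests", {
  a <- render_scene_from_seed("neurofibroma", 555, size = test_scene_size,
                              axes_range = c(25, 35), marker_radius = 14)
  b <- render_scene_from_seed("neurofibroma", 555, size = test_scene_size,
                              axes_range = c(25, 35), marker_radius = 14)
  expect_identical(a$images, b$images)
  expect_identical(render_cohort("nf1_2023", seed = 3),
                   render_cohort("nf1_2023", seed = 3))
})
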