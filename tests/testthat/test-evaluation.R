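test_that("sensitivity and specificity follow the count ratios", {
  expect_equal(sensitivity(list(tp = 47, fn = 3, fp = 0, tn = 0)), 94.0)
  expect_equal(sensitivity(list(tp = 61, fn = 4, fp = 0, tn = 0)),
               100 * 61 / 65, tolerance = 1e-12)
  expect_equal(round(sensitivity(list(tp = 61, fn = 4, fp = 0, tn = 0)), 2),
               93.85)
  expect_equal(sensitivity(list(tp = 5, fn = 0, fp = 2, tn = 2)), 100)
  expect_equal(specificity(list(tn = 19, fp = 1, tp = 0, fn = 0)), 95.0)
  expect_equal(round(specificity(list(tn = 139, fp = 27, tp = 0, fn = 0)), 2),
               83.73)
  expect_equal(specificity(list(tn = 6, fp = 0, tp = 1, fn = 1)), 100)
  expect_error(sensitivity(list(tp = 0, fn = 0, fp = 1, tn = 1)),
               class = "nf_format_error")
  expect_error(specificity(list(tp = 1, fn = 1, fp = 0, tn = 0)),
               class = "nf_format_error")

  # invariance to duplicating every observation
  c1 <- list(tp = 9, fn = 2, fp = 3, tn = 11)
  c2 <- lapply(c1, `*`, 2)
  expect_equal(sensitivity(c1), sensitivity(c2))
  expect_equal(specificity(c1), specificity(c2))
})

test_that("wilson_ci matches the closed form and prop.test oracle", {
  ci <- wilson_ci(9, 10, 0.95)
  expect_equal(ci, c(59.6, 98.2), tolerance = 0.002)
  expect_equal(wilson_ci(0, 15)[1], 0)
  expect_equal(wilson_ci(15, 15)[2], 100)

  # independent oracle: prop.test without continuity correction computes
  # the Wilson score interval
  set.seed(6)
  for (i in 1:25) {
    n <- sample(5:400, 1)
    x <- sample(0:n, 1)
    lv <- sample(c(0.9, 0.95, 0.99), 1)
    ours <- wilson_ci(x, n, lv)
    oracle <- 100 * stats::prop.test(x, n, conf.level = lv,
                                     correct = FALSE)$conf.int
    expect_equal(ours, as.numeric(oracle), tolerance = 1e-9)
  }

  # interval width shrinks toward zero as n grows at fixed proportion
  widths <- vapply(c(10, 100, 1000, 1e5), function(n)
    diff(wilson_ci(round(0.8 * n), n)), numeric(1))
  expect_true(all(diff(widths) < 0))
  expect_lt(widths[4], 0.5)
})

test_that("threshold_sweep agrees with exhaustive brute-force enumeration", {
  # separable toy: a perfect threshold exists
  sw <- threshold_sweep(c(3, 4), c(1, 2))
  expect_true(any(sw$sensitivity == 100 & sw$specificity == 100))

  # interleaved case and random cases vs brute force over a fine grid
  brute_best <- function(pos, neg) {
    grid <- sort(unique(c(pos, neg)))
    cand <- c(grid[1] - 1, grid + 1e-9, grid - 1e-9, grid[length(grid)] + 1)
    j <- vapply(cand, function(t)
      100 * mean(pos > t) + 100 * mean(neg <= t) - 100, numeric(1))
    max(j)
  }
  set.seed(13)
  cases <- c(list(list(pos = c(1, 3), neg = c(2, 4))),
             lapply(1:10, function(i)
               list(pos = round(runif(sample(2:20, 1)), 2),
                    neg = round(runif(sample(2:20, 1)), 2))))
  for (cs in cases) {
    best <- best_threshold(cs$pos, cs$neg)
    expect_equal(best$youden, brute_best(cs$pos, cs$neg), tolerance = 1e-6)
  }

  # identical lists: an uninformative parameter has best Youden J = 0
  expect_equal(best_threshold(c(1, 2, 3), c(1, 2, 3))$youden, 0)
})

test_that("swapping groups swaps sensitivity and specificity", {
  set.seed(21)
  pos <- runif(15); neg <- runif(12)
  sw_ab <- threshold_sweep(pos, neg, "above")
  sw_ba <- threshold_sweep(neg, pos, "below")
  # same thresholds; the two rates trade places (no ties at midpoints)
  expect_equal(sw_ab$threshold, sw_ba$threshold)
  expect_equal(sw_ab$sensitivity, sw_ba$specificity)
  expect_equal(sw_ab$specificity, sw_ba$sensitivity)
  expect_equal(best_threshold(pos, neg, "above")$youden,
               best_threshold(neg, pos, "below")$youden)
})

make_feature_df <- function(values) {
  # minimal feature table: one parameter value reused for all four columns
  do.call(rbind, lapply(names(values), function(cl) {
    data.frame(class_label = cl,
               G526_lesion_mean = values[[cl]],
               G526_lesion_mean_min5 = values[[cl]],
               pprime_mean = values[[cl]],
               pprime_mean_min5 = values[[cl]],
               stringsAsFactors = FALSE)
  }))
}

test_that("build_comparison_table mirrors the study's row structure", {
  set.seed(31)
  # fully separated classes: NF1-related higher
  vals <- list(cafe_au_lait = rnorm(25, 10, 0.1),
               neurofibroma = rnorm(65, 9, 0.1),
               dermatofibroma = rnorm(16, 2, 0.1),
               intradermal_nevus = rnorm(4, 2, 0.1),
               junctional_nevus = rnorm(129, 2, 0.1),
               lentigo_solaris = rnorm(17, 2, 0.1))
  tab <- build_comparison_table(make_feature_df(vals))
  expect_equal(nrow(tab), 12) # 3 positive groupings x 4 parameters
  expect_true(all(tab$sensitivity == 100))
  expect_true(all(tab$spec_all_non_nf1 == 100))
  expect_true(all(tab$spec_junctional_nevus == 100))
  expect_true(all(tab$sens_ci_high <= 100 & tab$sens_ci_low >= 0))
  expect_setequal(unique(tab$positive_group),
                  c("cafe_au_lait", "neurofibroma", "all_nf1"))

  # a missing positive class skips its rows with a warning
  vals2 <- vals; vals2$cafe_au_lait <- NULL
  expect_warning(tab2 <- build_comparison_table(make_feature_df(vals2)),
                 "cafe_au_lait")
  expect_equal(nrow(tab2), 8)

  # single-class input refuses evaluation
  expect_error(
    cmd_evaluate(cbind(make_feature_df(vals["cafe_au_lait"]),
                       status = "ok")),
    class = "nf_format_error")
})

test_that("group_statistics summarizes each class present", {
  set.seed(41)
  ft <- do.call(rbind, lapply(c("cafe_au_lait", "junctional_nevus"),
    function(cl) data.frame(class_label = cl,
                            AF405_lesion_mean = rnorm(30, 0.2, 0.02),
                            G526_lesion_mean_min5 = rnorm(30, 0.3, 0.02),
                            pprime_mean = rnorm(30, -0.2, 0.02),
                            pprime_mean_min5 = rnorm(30, -0.3, 0.02),
                            stringsAsFactors = FALSE)))
  gs <- group_statistics(ft)
  expect_equal(nrow(gs), 2)
  expect_equal(gs$n, c(30, 30))
  cafe <- ft[ft$class_label == "cafe_au_lait", ]
  expect_equal(gs$af_mean[1], mean(cafe$AF405_lesion_mean))
  expect_equal(gs$gmin5_sd[1], sd(cafe$G526_lesion_mean_min5))
  expect_equal(gs$pmin5_mean[1], mean(cafe$pprime_mean_min5))
})
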