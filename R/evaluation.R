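# Univariate threshold classification of lesion groups and
# sensitivity/specificity reporting with Wilson confidence intervals.

.check_counts <- function(counts) {
  need <- c("tp", "fp", "tn", "fn")
  if (!all(need %in% names(counts)))
    .nf_error("counts must name tp, fp, tn, fn", "nf_format_error")
  if (any(unlist(counts[need]) < 0))
    .nf_error("counts must be non-negative", "nf_format_error")
  counts
}

#' Sensitivity (true-positive rate, percent)
#'
#' `100 * TP / (TP + FN)`.
#'
#' @param counts List or named vector with `tp`, `fp`, `tn`, `fn`.
#' @return Sensitivity in percent.
#' @export
sensitivity <- function(counts) {
  counts <- .check_counts(counts)
  den <- counts[["tp"]] + counts[["fn"]]
  if (den == 0) .nf_error("sensitivity undefined: no positives", "nf_format_error")
  100 * counts[["tp"]] / den
}

#' Specificity (true-negative rate, percent)
#'
#' `100 * TN / (TN + FP)`.
#'
#' @param counts List or named vector with `tp`, `fp`, `tn`, `fn`.
#' @return Specificity in percent.
#' @export
specificity <- function(counts) {
  counts <- .check_counts(counts)
  den <- counts[["tn"]] + counts[["fp"]]
  if (den == 0) .nf_error("specificity undefined: no negatives", "nf_format_error")
  100 * counts[["tn"]] / den
}

#' Wilson score confidence interval, in percent
#'
#' @param successes Number of successes.
#' @param n Number of trials (> 0).
#' @param level Confidence level. Default 0.95.
#' @return `c(low, high)` in percent.
#' @export
wilson_ci <- function(successes, n, level = 0.95) {
  if (n <= 0) .nf_error("n must be positive", "nf_format_error")
  if (successes < 0 || successes > n)
    .nf_error("successes must lie in [0, n]", "nf_format_error")
  z <- qnorm(1 - (1 - level) / 2)
  p <- successes / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- (z / denom) * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  100 * c(max(0, center - half), min(1, center + half))
}

#' Sweep candidate thresholds between two groups
#'
#' Evaluates sensitivity and specificity at every midpoint between
#' adjacent distinct values of the pooled samples (plus one threshold
#' below the minimum and one above the maximum). With
#' `direction = "above"` positives are classified positive when their
#' value exceeds the threshold (NF1-related lesions score higher on all
#' four parameters); `"below"` inverts the rule.
#'
#' @param pos_values,neg_values Numeric vectors (non-empty) of the
#'   parameter for the positive and negative group.
#' @param direction `"above"` (default) or `"below"`.
#' @return Data frame with `threshold`, `sensitivity`, `specificity`,
#'   `youden` (J = sens + spec - 100).
#' @export
threshold_sweep <- function(pos_values, neg_values,
                            direction = c("above", "below")) {
  direction <- match.arg(direction)
  if (length(pos_values) == 0 || length(neg_values) == 0)
    .nf_error("both groups must be non-empty", "nf_format_error")
  pooled <- sort(unique(c(pos_values, neg_values)))
  mids <- if (length(pooled) > 1) {
    (pooled[-1] + pooled[-length(pooled)]) / 2
  } else numeric(0)
  span <- max(diff(range(pooled)), 1)
  thresholds <- c(pooled[1] - span / 100, mids,
                  pooled[length(pooled)] + span / 100)
  np <- length(pos_values); nn <- length(neg_values)
  res <- lapply(thresholds, function(t) {
    if (direction == "above") {
      tp <- sum(pos_values > t); fp <- sum(neg_values > t)
    } else {
      tp <- sum(pos_values < t); fp <- sum(neg_values < t)
    }
    c(threshold = t, sensitivity = 100 * tp / np,
      specificity = 100 * (nn - fp) / nn)
  })
  out <- as.data.frame(do.call(rbind, res))
  out$youden <- out$sensitivity + out$specificity - 100
  out
}

#' Select the best threshold by Youden's J
#'
#' Ties in J are broken toward higher sensitivity.
#'
#' @inheritParams threshold_sweep
#' @return One row of the [threshold_sweep()] table.
#' @export
best_threshold <- function(pos_values, neg_values,
                           direction = c("above", "below")) {
  sweep <- threshold_sweep(pos_values, neg_values, direction)
  jmax <- max(sweep$youden)
  cand <- sweep[sweep$youden >= jmax - 1e-9, ]
  cand[which.max(cand$sensitivity), ]
}

.parameter_columns <- c(
  G_lesion_mean = "G526_lesion_mean",
  G_lesion_min5 = "G526_lesion_mean_min5",
  pprime_mean = "pprime_mean",
  pprime_min5 = "pprime_mean_min5"
)

#' Evaluation parameters and their feature-table columns
#' @return Named character vector mapping parameter names to columns.
#' @export
evaluation_parameters <- function() .parameter_columns

#' Build the sensitivity/specificity comparison table
#'
#' For each positive grouping (cafe-au-lait macules, neurofibromas, all
#' NF1-related lesions) and each of the four parameters (mean of
#' G(lesion), mean of min-5% G(lesion), mean of p-prime, mean of min-5%
#' p-prime), selects the threshold maximizing Youden's J against the
#' pooled non-NF1 set, then reports one sensitivity (on the positives) and
#' the specificity against the pooled set and against each non-NF1 class
#' at that shared threshold, all with Wilson confidence intervals.
#'
#' @param feature_table Data frame of per-lesion feature rows
#'   (see [features_as_row()]) with a `class_label` column.
#' @param level Confidence level for the Wilson intervals. Default 0.95.
#' @param direction Classification direction, see [threshold_sweep()].
#' @return Data frame with one row per positive grouping x parameter:
#'   threshold, sensitivity with CI, and specificity with CI for the
#'   pooled comparison group and for each non-NF1 class.
#' @export
build_comparison_table <- function(feature_table, level = 0.95,
                                   direction = "above") {
  ft <- feature_table[!is.na(feature_table$class_label), , drop = FALSE]
  neg_classes <- setdiff(lesion_classes(), nf1_classes())
  neg_all <- ft[ft$class_label %in% neg_classes, , drop = FALSE]
  if (nrow(neg_all) == 0)
    .nf_error("no non-NF1 lesions in the feature table", "nf_format_error")
  pos_groups <- list(cafe_au_lait = "cafe_au_lait",
                     neurofibroma = "neurofibroma",
                     all_nf1 = nf1_classes())
  rows <- list()
  for (gname in names(pos_groups)) {
    pos <- ft[ft$class_label %in% pos_groups[[gname]], , drop = FALSE]
    if (nrow(pos) == 0) {
      warning(sprintf("no '%s' lesions; rows skipped", gname))
      next
    }
    for (pname in names(.parameter_columns)) {
      col <- .parameter_columns[[pname]]
      pv <- pos[[col]]; nv <- neg_all[[col]]
      pv <- pv[is.finite(pv)]; nv <- nv[is.finite(nv)]
      if (length(pv) == 0 || length(nv) == 0) {
        warning(sprintf("no finite values for %s/%s; row skipped",
                        gname, pname))
        next
      }
      best <- best_threshold(pv, nv, direction)
      thr <- best$threshold
      classify_pos <- function(v) if (direction == "above") v > thr else v < thr
      tp <- sum(classify_pos(pv))
      sens <- 100 * tp / length(pv)
      sci <- wilson_ci(tp, length(pv), level)
      row <- data.frame(
        positive_group = gname, parameter = pname, threshold = thr,
        direction = direction, n_pos = length(pv),
        sensitivity = sens, sens_ci_low = sci[1], sens_ci_high = sci[2],
        stringsAsFactors = FALSE)
      spec_groups <- c(list(all_non_nf1 = neg_classes),
                       stats::setNames(as.list(neg_classes), neg_classes))
      for (sg in names(spec_groups)) {
        gneg <- ft[ft$class_label %in% spec_groups[[sg]], , drop = FALSE]
        v <- gneg[[col]]; v <- v[is.finite(v)]
        if (length(v) == 0) {
          warning(sprintf("comparison class '%s' missing", sg))
          row[[paste0("spec_", sg)]] <- NA_real_
          row[[paste0("spec_", sg, "_ci_low")]] <- NA_real_
          row[[paste0("spec_", sg, "_ci_high")]] <- NA_real_
          next
        }
        tn <- sum(!classify_pos(v))
        ci <- wilson_ci(tn, length(v), level)
        row[[paste0("spec_", sg)]] <- 100 * tn / length(v)
        row[[paste0("spec_", sg, "_ci_low")]] <- ci[1]
        row[[paste0("spec_", sg, "_ci_high")]] <- ci[2]
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  do.call(rbind, rows)
}

#' Per-class group statistics of the headline parameters
#'
#' Mean and SD, per lesion class, of the three reported statistics: mean
#' AF(lesion), mean of min-5% G(lesion), and mean of min-5% p-prime (plus
#' the plain p-prime mean).
#'
#' @param feature_table Data frame of per-lesion feature rows.
#' @return Data frame with one row per class present in the table.
#' @export
group_statistics <- function(feature_table) {
  cols <- c(af = "AF405_lesion_mean",
            gmin5 = "G526_lesion_mean_min5",
            pprime = "pprime_mean",
            pmin5 = "pprime_mean_min5")
  classes <- intersect(lesion_classes(), unique(feature_table$class_label))
  rows <- lapply(classes, function(cl) {
    sub <- feature_table[feature_table$class_label == cl, , drop = FALSE]
    out <- data.frame(class_label = cl, n = nrow(sub),
                      stringsAsFactors = FALSE)
    for (nm in names(cols)) {
      v <- sub[[cols[[nm]]]]
      v <- v[is.finite(v)]
      out[[paste0(nm, "_mean")]] <- mean(v)
      out[[paste0(nm, "_sd")]] <- stats::sd(v)
    }
    out
  })
  do.call(rbind, rows)
}
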