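# Per-region summary statistics, the per-pixel p-prime contrast map, and
# the per-lesion feature vector.

.stats_from_values <- function(v) {
  n <- length(v)
  if (n == 0) .nf_error("empty region", "nf_format_error")
  m <- mean(v)
  va <- mean((v - m)^2) # population variance, fixed for determinism
  k <- ceiling(0.05 * n)
  sv <- sort(v)
  structure(list(
    mean = m, variance = va, sd = sqrt(va),
    mean_min5 = mean(sv[seq_len(k)]),
    mean_max5 = mean(sv[seq.int(n - k + 1L, n)]),
    n_pixels = n,
    flagged_small = n < 20
  ), class = "region_stats")
}

#' Summary statistics of pixel values within a mask
#'
#' Computes the mean, population variance, SD, and the means of the
#' minimum and maximum 5% of the pixel values (k = ceiling(0.05 n) values
#' in each tail). The min-5% mean is the study's robust lesion statistic:
#' imperfect masks admit brighter skin pixels, which the low tail
#' excludes.
#'
#' @param plane Numeric matrix.
#' @param mask Logical matrix, non-empty.
#' @return A `region_stats` list: `mean`, `variance`, `sd`, `mean_min5`,
#'   `mean_max5`, `n_pixels`, and `flagged_small` (`TRUE` when fewer than
#'   20 pixels).
#' @export
region_stats <- function(plane, mask) {
  if (!any(mask)) .nf_error("empty mask", "nf_format_error")
  .stats_from_values(plane[mask])
}

#' @export
print.region_stats <- function(x, ...) {
  cat(sprintf("region_stats: n=%d mean=%.4f sd=%.4f min5=%.4f max5=%.4f\n",
              x$n_pixels, x$mean, x$sd, x$mean_min5, x$mean_max5))
  invisible(x)
}

#' Per-pixel p-prime chromophore-contrast map
#'
#' For each lesion pixel computes
#' `p' = log10( (G_pix * mean R_skin * mean IR_skin) /
#'              (mean G_skin * R_pix * IR_pix) )`,
#' the log10 ratio of lesion-to-skin reflectance products across the
#' 526/663/964 nm bands. Skin terms are the means over the skin annulus.
#' All six factors are clamped below at `eps` before division, so the map
#' is finite even on underexposed pixels (clamping is reported).
#'
#' @param g_plane,r_plane,ir_plane Aligned channel planes (G526, R663,
#'   IR964).
#' @param lesion_mask Logical lesion mask on the same frame.
#' @param skin_means Named numeric vector with skin means for `G526`,
#'   `R663`, `IR964` (e.g. from [segment_scene()]'s `skin_stats$mean`).
#' @param eps Lower clamp for every factor. Default `1e-4`.
#' @return List with `values` (p-prime per lesion pixel, in mask order),
#'   `skin_means`, and `n_clamped`.
#' @export
p_prime_map <- function(g_plane, r_plane, ir_plane, lesion_mask,
                        skin_means, eps = 1e-4) {
  need <- c("G526", "R663", "IR964")
  if (!all(need %in% names(skin_means)))
    .nf_error("skin_means must name G526, R663 and IR964", "nf_format_error")
  if (any(skin_means[need] <= eps))
    .nf_error("invalid skin: a skin-band mean is at or below eps",
              "nf_invalid_skin")
  g <- g_plane[lesion_mask]
  r <- r_plane[lesion_mask]
  ir <- ir_plane[lesion_mask]
  n_clamped <- sum(g < eps) + sum(r < eps) + sum(ir < eps)
  g <- pmax(g, eps); r <- pmax(r, eps); ir <- pmax(ir, eps)
  vals <- log10((g * skin_means[["R663"]] * skin_means[["IR964"]]) /
                  (skin_means[["G526"]] * r * ir))
  list(values = vals, skin_means = skin_means[need], n_clamped = n_clamped)
}

#' Compute the per-lesion feature vector
#'
#' For every band, region statistics over the lesion mask (AF(lesion),
#' G(lesion), R(lesion), IR(lesion)) and over the skin annulus (AF(skin),
#' G(skin), R(skin), IR(skin)); plus the p-prime map over the lesion mask
#' and its region statistics. All bands share the same lesion mask.
#'
#' @param mset Aligned `multispectral_set`.
#' @param seg A `segmentation_result` from [segment_scene()].
#' @param entry Optional manifest entry (list/row with `lesion_id`,
#'   `class_label`) carried into the result.
#' @return A `lesion_features` list: `bands` (per band: `lesion` and
#'   `skin` `region_stats`), `pprime` (`region_stats` of the map),
#'   `pprime_map`, `lesion_id`, `class_label`, `mask_source`, `flags`.
#' @export
compute_features <- function(mset, seg, entry = NULL) {
  stopifnot(inherits(mset, "multispectral_set"), isTRUE(mset$aligned))
  if (!any(seg$lesion_mask))
    .nf_error("empty lesion mask", "nf_segmentation_failed")
  bands <- lapply(spectral_bands(), function(b) {
    list(lesion = region_stats(mset$planes[[b]], seg$lesion_mask),
         skin = region_stats(mset$planes[[b]], seg$skin_mask))
  })
  names(bands) <- spectral_bands()
  pmap <- p_prime_map(mset$planes[["G526"]], mset$planes[["R663"]],
                      mset$planes[["IR964"]], seg$lesion_mask,
                      skin_means = seg$skin_stats$mean)
  flags <- seg$flags
  if (pmap$n_clamped > 0)
    flags <- c(flags, sprintf("pprime_clamped:%d", pmap$n_clamped))
  structure(list(
    bands = bands,
    pprime = .stats_from_values(pmap$values),
    pprime_map = pmap,
    lesion_id = if (!is.null(entry)) entry$lesion_id else mset$lesion_id,
    class_label = if (!is.null(entry)) entry$class_label else NA_character_,
    mask_source = seg$mask_source,
    flags = flags
  ), class = "lesion_features")
}

.stat_names <- c("mean", "variance", "sd", "mean_min5", "mean_max5", "n_pixels")

#' Flatten lesion features into a one-row data frame
#'
#' Columns are named `<band>_<region>_<stat>` (e.g.
#' `G526_lesion_mean_min5`) plus `pprime_<stat>`, with `lesion_id`,
#' `class_label`, `mask_source` and `flags` bookkeeping columns.
#'
#' @param features A `lesion_features` object.
#' @return One-row data frame.
#' @export
features_as_row <- function(features) {
  out <- list(lesion_id = features$lesion_id,
              class_label = features$class_label)
  for (b in spectral_bands()) {
    for (region in c("lesion", "skin")) {
      st <- features$bands[[b]][[region]]
      for (s in .stat_names)
        out[[paste(b, region, s, sep = "_")]] <- st[[s]]
    }
  }
  for (s in .stat_names)
    out[[paste0("pprime_", s)]] <- features$pprime[[s]]
  out$mask_source <- features$mask_source
  out$flags <- paste(features$flags, collapse = ";")
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Export a p-prime map as a 32-bit float TIFF image
#'
#' Renders the per-pixel p-prime values of the lesion into the full image
#' frame (background `NA` encoded as the `background` value), for
#' inspection in external viewers.
#'
#' @param pmap Result of [p_prime_map()].
#' @param lesion_mask The mask the map was computed over.
#' @param path Output TIFF path.
#' @param background Value written outside the lesion. Default 0.
#' @return `path`, invisibly.
#' @export
write_pprime_tiff <- function(pmap, lesion_mask, path, background = 0) {
  img <- matrix(background, nrow(lesion_mask), ncol(lesion_mask))
  img[lesion_mask] <- pmap$values
  write_tiff(img, path, bits = 32)
}
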