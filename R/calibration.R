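# Class calibrations: group mean and SD of the three reported lesion
# statistics, per lesion class. These are the targets the synthetic
# generator reproduces at cohort level:
#   af    — mean autofluorescence intensity of the lesion, AF(lesion)
#   gmin5 — mean of the minimum 5% of G(lesion) (526 nm reflectance)
#   pmin5 — mean of the minimum 5% of the per-pixel p-prime map
# All values in arbitrary units on the [0,1] (log10 for p-prime) scale.

.default_calibrations <- data.frame(
  class_label = c("cafe_au_lait", "neurofibroma", "dermatofibroma",
                  "intradermal_nevus", "junctional_nevus", "lentigo_solaris"),
  af_mean    = c(0.27, 0.25, 0.15, 0.19, 0.17, 0.20),
  af_sd      = c(0.10, 0.11, 0.11, 0.08, 0.07, 0.08),
  gmin5_mean = c(0.41, 0.33, 0.18, 0.09, 0.13, 0.20),
  gmin5_sd   = c(0.07, 0.10, 0.10, 0.07, 0.07, 0.09),
  pmin5_mean = c(-0.16, -0.15, -0.38, -0.57, -0.38, -0.25),
  pmin5_sd   = c(0.05, 0.08, 0.11, 0.25, 0.09, 0.10),
  stringsAsFactors = FALSE
)

# Physical clamps applied to drawn per-lesion targets. Lower bounds on the
# intensity targets keep every lesion pixel strictly above the fiducial
# marker intensity (0.02 a.u.); the p-prime upper bound keeps the lesion
# darker than the perilesional skin at 526 nm.
.target_bounds <- list(
  af = c(0.05, 0.97), gmin5 = c(0.05, 0.95), pmin5 = c(-1.6, -0.02)
)

#' Calibration table of per-class group statistics
#'
#' Returns the per-class means and standard deviations of the three group
#' statistics the synthetic generator is calibrated to: mean
#' autofluorescence intensity AF(lesion), mean of the minimum 5% of
#' G(lesion), and mean of the minimum 5% of the p-prime parameter.
#'
#' @return Data frame with one row per lesion class.
#' @export
class_calibrations <- function() .default_calibrations

#' Draw per-lesion statistic targets for one class
#'
#' Draws `n` triples (af, gmin5, pmin5) from independent Normals with the
#' calibrated class mean and SD, clamped to physically valid ranges
#' (intensities must stay above the marker intensity and below full
#' scale; p-prime must remain negative so the lesion is darker than skin
#' at 526 nm). Uses the current R RNG state; seed beforehand for
#' reproducibility.
#'
#' @param calibration One row of [class_calibrations()] (or a list with
#'   fields `af_mean`, `af_sd`, `gmin5_mean`, `gmin5_sd`, `pmin5_mean`,
#'   `pmin5_sd`).
#' @param n Number of lesions to draw targets for.
#' @return Data frame with columns `af`, `gmin5`, `pmin5`.
#' @export
sample_lesion_targets <- function(calibration, n = 1) {
  if (is.character(calibration)) {
    cal <- .default_calibrations
    row <- cal[cal$class_label == calibration, ]
    if (nrow(row) != 1)
      .nf_error(sprintf("unknown class '%s'", calibration), "nf_format_error")
    calibration <- row
  }
  stopifnot(calibration$af_sd >= 0, calibration$gmin5_sd >= 0,
            calibration$pmin5_sd >= 0)
  clamp <- function(x, b) pmin(pmax(x, b[1]), b[2])
  data.frame(
    af    = clamp(rnorm(n, calibration$af_mean, calibration$af_sd),
                  .target_bounds$af),
    gmin5 = clamp(rnorm(n, calibration$gmin5_mean, calibration$gmin5_sd),
                  .target_bounds$gmin5),
    pmin5 = clamp(rnorm(n, calibration$pmin5_mean, calibration$pmin5_sd),
                  .target_bounds$pmin5)
  )
}
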