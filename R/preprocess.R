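# Marker detection, translational stabilization, and threshold-based
# segmentation into marker / perilesional-skin / lesion regions.

#' Detect the fiducial marker in a channel plane
#'
#' Thresholds the plane at the given intensity quantile (the darkest
#' pixels), discards connected components larger than `max_area_frac` of
#' the image (degenerate thresholds), keeps the largest remaining
#' component, and fills its holes. The centroid is the mean of the member
#' pixel coordinates (subpixel).
#'
#' @param plane Numeric matrix in `[0, 1]`.
#' @param darkness_quantile Intensity quantile defining "darkest pixels";
#'   must be in `(0, 0.05]`. Default 0.005.
#' @param max_area_frac Components covering more than this fraction of the
#'   image are rejected. Default 0.05.
#' @return List with `mask` (logical matrix, one filled component),
#'   `centroid` (`c(row, col)`, subpixel) and `darkness_quantile`.
#' @export
detect_marker <- function(plane, darkness_quantile = 0.005,
                          max_area_frac = 0.05) {
  stopifnot(darkness_quantile > 0, darkness_quantile <= 0.05)
  thr <- quantile(plane, darkness_quantile, names = FALSE)
  cand <- plane <= thr
  # noise keeps a random ~30% of marker pixels above the threshold; a
  # 1 px closing bridges those gaps so the marker stays one component
  cand <- .binary_erode(.binary_dilate(cand, 1), 1)
  lab <- .cc_label(cand)
  ncomp <- attr(lab, "n_components")
  if (ncomp == 0)
    .nf_error("marker not found: no dark pixels", "nf_marker_not_found")
  sizes <- tabulate(lab[lab > 0], nbins = ncomp)
  sizes[sizes > max_area_frac * length(plane)] <- 0L
  if (all(sizes == 0))
    .nf_error("marker not found: only degenerate dark components",
              "nf_marker_not_found")
  best <- which.max(sizes)
  mask <- .fill_holes(lab == best)
  idx <- which(mask, arr.ind = TRUE)
  list(mask = mask, centroid = colMeans(idx)[c("row", "col")],
       darkness_quantile = darkness_quantile)
}

#' Stabilize a multispectral set by marker superposition
#'
#' Detects the marker in every band plane, translates each plane by the
#' integer-rounded difference between its marker centroid and the
#' reference band's (G526), and crops all planes to the common overlapping
#' region.
#'
#' @param mset A `multispectral_set` (see [multispectral_set()]).
#' @param darkness_quantile,max_area_frac Passed to [detect_marker()].
#' @return The aligned `multispectral_set` with attributes `shifts` (named
#'   list of recovered integer `c(dy, dx)` per band) and `window` (list
#'   with `rows`, `cols`: the retained coordinate ranges in the reference
#'   frame, usable to crop ground-truth masks via [crop_to_window()]).
#' @export
stabilize <- function(mset, darkness_quantile = 0.005, max_area_frac = 0.05) {
  stopifnot(inherits(mset, "multispectral_set"))
  bands <- spectral_bands()
  cents <- lapply(mset$planes, function(p)
    detect_marker(p, darkness_quantile, max_area_frac)$centroid)
  ref <- cents[["G526"]]
  shifts <- lapply(cents, function(ct) as.integer(round(ct - ref)))
  nr <- nrow(mset$planes[[1]]); nc <- ncol(mset$planes[[1]])
  dys <- vapply(shifts, `[`, integer(1), 1)
  dxs <- vapply(shifts, `[`, integer(1), 2)
  rows <- max(1, 1 - min(dys)):(min(nr, nr - max(dys)))
  cols <- max(1, 1 - min(dxs)):(min(nc, nc - max(dxs)))
  if (length(rows) < 32 || length(cols) < 32)
    .nf_error("stabilization left too small a common region", "nf_marker_not_found")
  planes <- lapply(bands, function(b) {
    s <- shifts[[b]]
    mset$planes[[b]][rows + s[1], cols + s[2], drop = FALSE]
  })
  names(planes) <- bands
  out <- structure(list(planes = planes, lesion_id = mset$lesion_id,
                        aligned = TRUE), class = "multispectral_set")
  attr(out, "shifts") <- shifts
  attr(out, "window") <- list(rows = rows, cols = cols)
  out
}

#' Crop a reference-frame mask to a stabilization window
#'
#' @param mask Logical matrix in the reference (G526) frame.
#' @param window `attr(aligned_set, "window")` from [stabilize()].
#' @return Cropped logical matrix matching the aligned planes.
#' @export
crop_to_window <- function(mask, window) {
  mask[window$rows, window$cols, drop = FALSE]
}

#' Estimate the perilesional skin intensity range around the marker
#'
#' The marker is placed on healthy skin next to the lesion, so the skin
#' level can be read from an annulus around it: the marker mask is dilated
#' by a disc of radius `dilation_factor` times the marker's equivalent
#' radius, and the annulus (dilation minus marker) provides the skin
#' pixels. The range is mean +/- `k` SD; a zero-variance annulus is
#' widened by 0.01 a.u.
#'
#' @param plane Channel plane (aligned frame).
#' @param marker_mask Marker mask from [detect_marker()] on the same frame.
#' @param dilation_factor Dilation radius in units of the marker
#'   equivalent radius. Default 2.
#' @param k Half-width of the range in annulus SDs. Default 2.
#' @param annulus Optional precomputed annulus mask (reused across bands).
#' @return List with `skin_mask` (the annulus), `skin_range`
#'   `c(low, high)`, `mean`, `sd`, and `border_clipped`.
#' @export
estimate_skin_range <- function(plane, marker_mask, dilation_factor = 2,
                                k = 2, annulus = NULL) {
  if (is.null(annulus))
    annulus <- skin_annulus(marker_mask, dilation_factor)
  border_clipped <- isTRUE(attr(annulus, "border_clipped"))
  px <- plane[annulus]
  if (length(px) < 10)
    .nf_error("skin annulus empty", "nf_segmentation_failed")
  mu <- mean(px); s <- stats::sd(px)
  if (!is.finite(s) || s < 1e-12) {
    rng <- c(mu - 0.01, mu + 0.01)
  } else {
    rng <- c(mu - k * s, mu + k * s)
  }
  list(skin_mask = annulus, skin_range = rng, mean = mu, sd = s,
       border_clipped = border_clipped)
}

#' Build the skin annulus around a marker mask
#'
#' The marker mask is dilated by `dilation_factor` equivalent radii; the
#' annulus is that dilation minus an inner guard zone (the marker dilated
#' by `inner_pad_frac` equivalent radii). The guard zone keeps dark
#' marker-rim pixels that the darkness threshold missed out of the skin
#' estimate.
#'
#' @param marker_mask Logical matrix.
#' @param dilation_factor Dilation radius in units of the marker
#'   equivalent radius.
#' @param inner_pad_frac Inner guard-zone width, in equivalent radii.
#' @return Logical annulus mask with attribute `border_clipped` (`TRUE`,
#'   with a warning, when the annulus touches the image border and was
#'   implicitly shrunk).
#' @export
skin_annulus <- function(marker_mask, dilation_factor = 2,
                         inner_pad_frac = 0.25) {
  req <- sqrt(sum(marker_mask) / pi)
  dil <- .binary_dilate(marker_mask, dilation_factor * req)
  inner <- .binary_dilate(marker_mask, inner_pad_frac * req)
  annulus <- dil & !inner
  attr(annulus, "dilated") <- dil
  nr <- nrow(annulus); nc <- ncol(annulus)
  clipped <- any(annulus[1, ]) || any(annulus[nr, ]) ||
    any(annulus[, 1]) || any(annulus[, nc])
  if (clipped)
    warning("skin annulus touches the image border; using the clipped annulus")
  structure(annulus, border_clipped = clipped)
}

#' Segment the lesion by thresholding below the skin range
#'
#' Lesion candidates are pixels darker than `skin_range[1]` (skin is
#' lighter than all lesions in these images), excluding the dilated marker
#' region. The largest connected component is kept, holes are filled, and
#' a morphological opening (disc, `opening_radius` px) removes speckle.
#' Segmentation is intended for the G526 plane (strongest lesion
#' contrast); the resulting mask is reused for all bands.
#'
#' @param plane Channel plane (aligned frame; normally G526).
#' @param marker_mask Marker mask on the same frame.
#' @param skin_range `c(low, high)` from [estimate_skin_range()].
#' @param dilation_factor Marker exclusion dilation (as in
#'   [estimate_skin_range()]).
#' @param opening_radius Disc radius of the final opening, px.
#' @param excl Optional precomputed marker exclusion mask (the dilated
#'   marker), reused from [skin_annulus()].
#' @return Logical lesion mask.
#' @export
segment_lesion <- function(plane, marker_mask, skin_range,
                           dilation_factor = 2, opening_radius = 2,
                           excl = NULL) {
  if (is.null(excl)) {
    req <- sqrt(sum(marker_mask) / pi)
    excl <- .binary_dilate(marker_mask, dilation_factor * req)
  }
  cand <- (plane < skin_range[1]) & !excl
  lab <- .cc_label(cand)
  ncomp <- attr(lab, "n_components")
  if (ncomp == 0)
    .nf_error("segmentation failed: no pixels below the skin range",
              "nf_segmentation_failed")
  sizes <- tabulate(lab[lab > 0], nbins = ncomp)
  mask <- .fill_holes(lab == which.max(sizes))
  if (opening_radius > 0) {
    mask <- .binary_dilate(.binary_erode(mask, opening_radius), opening_radius)
  }
  if (!any(mask))
    .nf_error("segmentation failed: mask empty after opening",
              "nf_segmentation_failed")
  mask
}

#' Load an external lesion mask override
#'
#' Reads a hand-drawn binary mask (e.g. exported from an annotation tool)
#' replacing the automatic segmentation: nonzero pixels become the lesion.
#'
#' @param path 8-bit single-channel PNG/TIFF; 0 = background.
#' @param expected_dim `c(rows, cols)` of the aligned planes.
#' @return Logical lesion mask.
#' @export
load_mask_override <- function(path, expected_dim) {
  img <- read_gray_image(path)
  if (!identical(dim(img), as.integer(expected_dim)) &&
      !identical(dim(img), as.numeric(expected_dim)) &&
      !all(dim(img) == expected_dim))
    .nf_error(sprintf("mask shape %s does not match expected %s",
                      paste(dim(img), collapse = "x"),
                      paste(expected_dim, collapse = "x")),
              "nf_format_error")
  mask <- img > 0
  if (!any(mask)) .nf_error("override mask is empty", "nf_format_error")
  mask
}

#' Segment an aligned multispectral set into marker, skin and lesion
#'
#' Orchestrates [detect_marker()] (on the aligned G526 plane),
#' [estimate_skin_range()] per band (one shared annulus), and
#' [segment_lesion()] on the G526 plane. An external mask, when given,
#' overrides the automatic lesion mask.
#'
#' @param mset Aligned `multispectral_set`.
#' @param params Preprocessing parameters, see [pipeline_config()].
#' @param override_mask Optional logical matrix replacing the automatic
#'   lesion segmentation.
#' @return A `segmentation_result`: list with `marker_mask`, `skin_mask`,
#'   `lesion_mask`, `skin_range` (per-band low/high matrix), `skin_stats`
#'   (per-band annulus mean/sd), `mask_source` and `flags` (e.g.
#'   `annulus_inflated` when one band's annulus SD exceeds 3x the median
#'   across bands, the signature of a marker placed too close to the
#'   lesion).
#' @export
segment_scene <- function(mset, params = pipeline_config(),
                          override_mask = NULL) {
  stopifnot(inherits(mset, "multispectral_set"), isTRUE(mset$aligned))
  det <- detect_marker(mset$planes[["G526"]], params$darkness_quantile,
                       params$max_area_frac)
  annulus <- skin_annulus(det$mask, params$dilation_factor)
  skin <- lapply(mset$planes, estimate_skin_range, marker_mask = det$mask,
                 dilation_factor = params$dilation_factor, k = params$skin_k,
                 annulus = annulus)
  sds <- vapply(skin, `[[`, numeric(1), "sd")
  flags <- character(0)
  inflated <- sds > 3 * median(sds)
  if (any(inflated))
    flags <- c(flags, paste0("annulus_inflated:",
                             paste(names(sds)[inflated], collapse = "+")))
  if (isTRUE(attr(annulus, "border_clipped")))
    flags <- c(flags, "annulus_border_clipped")
  if (is.null(override_mask)) {
    lesion <- segment_lesion(mset$planes[["G526"]], det$mask,
                             skin[["G526"]]$skin_range,
                             params$dilation_factor, params$opening_radius,
                             excl = attr(annulus, "dilated"))
    mask_source <- "auto"
  } else {
    if (!all(dim(override_mask) == dim(mset$planes[[1]])))
      .nf_error("override mask shape mismatch", "nf_format_error")
    lesion <- override_mask & TRUE
    mask_source <- "override"
  }
  # keep the three masks pairwise disjoint; an override mask wins, so the
  # marker/skin masks yield where they overlap it (its pixel count is the
  # annotator's choice and must survive into the region statistics)
  structure(list(
    marker_mask = det$mask & !lesion,
    skin_mask = annulus & !lesion,
    lesion_mask = lesion,
    skin_range = vapply(skin, `[[`, numeric(2), "skin_range"),
    skin_stats = list(mean = vapply(skin, `[[`, numeric(1), "mean"),
                      sd = sds),
    mask_source = mask_source,
    flags = flags
  ), class = "segmentation_result")
}
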