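# Synthetic multispectral scene renderer.
#
# A scene is a light skin background, a darker elliptical lesion, and a
# near-black circular fiducial marker near (but disjoint from) the lesion,
# rendered in all four bands with per-band integer translation offsets and
# additive Gaussian noise. Lesion pixel fields are constructed so that,
# given the ground-truth masks and before noise, the three calibrated
# statistics (mean AF, min-5% of G, min-5% of p-prime) hit the drawn
# per-lesion targets exactly; see the methods vignette for the algebra.

# Smooth Gaussian texture: coarse white noise, bilinearly upsampled, then
# standardized to mean 0 / sd 1 over the full image.
.smooth_field <- function(nr, nc, spacing = 32) {
  gr <- ceiling(nr / spacing) + 2L
  gc <- ceiling(nc / spacing) + 2L
  g <- matrix(rnorm(gr * gc), gr, gc)
  ry <- (seq_len(nr) - 1) / spacing
  cx <- (seq_len(nc) - 1) / spacing
  i0 <- pmin(floor(ry), gr - 2); fy <- ry - i0
  j0 <- pmin(floor(cx), gc - 2); fx <- cx - j0
  I0 <- matrix(as.integer(i0) + 1L, nr, nc)
  J0 <- matrix(as.integer(j0) + 1L, nr, nc, byrow = TRUE)
  FY <- matrix(fy, nr, nc)
  FX <- matrix(fx, nr, nc, byrow = TRUE)
  idx <- function(I, J) matrix(g[cbind(as.vector(I), as.vector(J))], nr, nc)
  f <- (1 - FY) * (1 - FX) * idx(I0, J0) +
    (1 - FY) * FX * idx(I0, J0 + 1L) +
    FY * (1 - FX) * idx(I0 + 1L, J0) +
    FY * FX * idx(I0 + 1L, J0 + 1L)
  (f - mean(f)) / stats::sd(f)
}

.ellipse_mask <- function(nr, nc, center, axes, rotation = 0) {
  Rm <- matrix(seq_len(nr), nr, nc) - center[1]
  Cm <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - center[2]
  u <- Cm * cos(rotation) + Rm * sin(rotation)
  v <- -Cm * sin(rotation) + Rm * cos(rotation)
  (u / axes[1])^2 + (v / axes[2])^2 <= 1
}

.disc_mask <- function(nr, nc, center, radius) {
  Rm <- matrix(seq_len(nr), nr, nc) - center[1]
  Cm <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - center[2]
  Rm^2 + Cm^2 <= radius^2
}

.shift_matrix <- function(mat, dy, dx, fill = 0) {
  nr <- nrow(mat); nc <- ncol(mat)
  out <- matrix(fill, nr, nc)
  rd <- max(1, 1 + dy):min(nr, nr + dy)
  cd <- max(1, 1 + dx):min(nc, nc + dx)
  if (length(rd) > 0 && length(cd) > 0)
    out[rd, cd] <- mat[rd - dy, cd - dx]
  out
}

#' Construct a synthetic scene specification
#'
#' Geometry, per-band skin base intensities, per-band integer translation
#' offsets and noise level for one synthetic scene. Defaults follow the
#' generator's stated world: 512 x 512 px, lesion semi-axes 40-80 px,
#' marker radius 24 px placed at least 30 px from the lesion boundary,
#' additive noise sd 0.01 a.u., marker intensity 0.02 a.u., and skin bases
#' 0.35 (AF), 0.60 (G526, replaced per-scene by the calibration), 0.70
#' (R663) and 0.65 (IR964) a.u.
#'
#' @param size Image size as `c(rows, cols)`, each >= 64.
#' @param lesion_center,lesion_axes,lesion_rotation Lesion ellipse.
#' @param marker_center,marker_radius Fiducial marker disc.
#' @param skin_base Named per-band skin intensities in a.u.
#' @param offsets Named list of per-band `c(dy, dx)` integer translations
#'   (`G526` is the reference and must be `c(0, 0)`; |dy|,|dx| <= 10).
#' @param noise_sd Additive Gaussian noise sd, a.u.
#' @param marker_intensity Marker intensity, a.u.
#' @param texture_spacing Control-point spacing of the smooth lesion
#'   texture, px.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(size = c(512, 512),
                       lesion_center = size / 2,
                       lesion_axes = c(60, 50),
                       lesion_rotation = 0,
                       marker_center = c(size[1] / 2, size[2] / 6),
                       marker_radius = 24,
                       skin_base = c(AF405 = 0.35, G526 = 0.60,
                                     R663 = 0.70, IR964 = 0.65),
                       offsets = list(AF405 = c(0, 0), G526 = c(0, 0),
                                      R663 = c(0, 0), IR964 = c(0, 0)),
                       noise_sd = 0.01,
                       marker_intensity = 0.02,
                       texture_spacing = 32) {
  stopifnot(all(size >= 64), marker_radius > 0, all(lesion_axes > 0))
  if (any(vapply(offsets, function(o) any(abs(o) > 10), logical(1))))
    .nf_error("per-band offsets must satisfy |dy|,|dx| <= 10 px", "nf_format_error")
  if (any(offsets$G526 != 0))
    .nf_error("G526 is the reference band; its offset must be (0, 0)", "nf_format_error")
  structure(list(size = size, lesion_center = lesion_center,
                 lesion_axes = lesion_axes, lesion_rotation = lesion_rotation,
                 marker_center = marker_center, marker_radius = marker_radius,
                 skin_base = skin_base, offsets = offsets, noise_sd = noise_sd,
                 marker_intensity = marker_intensity,
                 texture_spacing = texture_spacing),
            class = "scene_spec")
}

#' Draw a random scene specification
#'
#' Samples lesion geometry (semi-axes uniform in `axes_range`, random
#' rotation), a marker position at least `marker_gap` px (edge to edge)
#' from the lesion and clear of the image border including the skin
#' annulus, and per-band integer offsets uniform on `[-5, 5]` px (the
#' reference band G526 stays at zero). Uses the current RNG state.
#'
#' @param size Image size `c(rows, cols)`.
#' @param axes_range Range of the lesion semi-axes, px. Defaults to
#'   40-80 px at 512 px resolution, scaled linearly with `min(size)` so
#'   scenes are resolution-consistent.
#' @param marker_radius Marker disc radius, px (default 24 at 512 px
#'   resolution, scaled with `min(size)`, at least 6).
#' @param marker_gap Minimum edge-to-edge distance marker to lesion, px
#'   (default 30, scaled, at least 10).
#' @param max_offset Maximum per-band |translation|, px.
#' @param ... Passed through to [scene_spec()].
#' @return A `scene_spec`.
#' @export
random_scene_spec <- function(size = c(512, 512), axes_range = NULL,
                              marker_radius = NULL, marker_gap = NULL,
                              max_offset = 5, ...) {
  scale <- min(size) / 512
  if (is.null(axes_range)) axes_range <- c(40, 80) * scale
  if (is.null(marker_radius)) marker_radius <- max(24 * scale, 6)
  if (is.null(marker_gap)) marker_gap <- max(30 * scale, 10)
  axes <- sort(runif(2, axes_range[1], axes_range[2]), decreasing = TRUE)
  rot <- runif(1, 0, pi)
  lc <- size / 2 + runif(2, -0.08, 0.08) * min(size)
  # border margin: marker + dilated skin annulus + max offset must stay
  # inside the image in every band
  margin <- 3 * marker_radius + max_offset + 2
  lo <- rep(margin + 1, 2); hi <- size - margin
  if (any(hi <= lo))
    .nf_error("image too small for marker/annulus geometry", "nf_format_error")
  mind <- max(axes) + marker_gap + marker_radius
  mc <- NULL
  for (i in 1:1000) {
    cand <- c(runif(1, lo[1], hi[1]), runif(1, lo[2], hi[2]))
    if (sqrt(sum((cand - lc)^2)) >= mind) { mc <- cand; break }
  }
  if (is.null(mc))
    .nf_error("could not place marker away from lesion", "nf_format_error")
  offs <- list(AF405 = sample(-max_offset:max_offset, 2, replace = TRUE),
               G526 = c(0, 0),
               R663 = sample(-max_offset:max_offset, 2, replace = TRUE),
               IR964 = sample(-max_offset:max_offset, 2, replace = TRUE))
  scene_spec(size = size, lesion_center = lc, lesion_axes = axes,
             lesion_rotation = rot, marker_center = mc,
             marker_radius = marker_radius, offsets = offs, ...)
}

#' Render one synthetic multispectral scene
#'
#' Builds the four raw RGB band images for one lesion plus ground truth.
#' Before noise, on the ground-truth masks: the lesion AF mean equals the
#' drawn `af` target exactly; the mean of the minimum 5% of lesion G
#' pixels equals `gmin5` exactly; and the skin G base is set to
#' `10^(m - pmin5)` (`m` = mean log10 of those same minimum-5% G pixels)
#' so the min-5% of the p-prime map is also exact when the R/IR lesion
#' contrast is neutral. R663/IR964 lesion pixels sit at the skin level
#' times a factor drawn from Normal(1, 0.02) (no significant lesion
#' contrast in those bands).
#'
#' @param spec A [scene_spec()].
#' @param targets One-row data frame from [sample_lesion_targets()].
#' @param neutral_r_ir If `TRUE`, fix the R/IR lesion factors at exactly 1.
#' @param fixed_skin_g Optional: force the G-band skin base instead of
#'   deriving it from the p-prime target. Errors if the `gmin5` target is
#'   not below it (infeasible calibration).
#' @return List with `images` (named list of RGB arrays, one per band) and
#'   `truth` (lesion/marker masks in the reference frame, per-band true
#'   offsets, drawn and achieved targets, final skin bases).
#' @export
render_scene <- function(spec, targets, neutral_r_ir = FALSE,
                         fixed_skin_g = NULL) {
  nr <- spec$size[1]; nc <- spec$size[2]
  E <- .ellipse_mask(nr, nc, spec$lesion_center, spec$lesion_axes,
                     spec$lesion_rotation)
  M <- .disc_mask(nr, nc, spec$marker_center, spec$marker_radius)
  if (any(E & M))
    .nf_error("marker overlaps lesion", "nf_calibration_error")
  nE <- sum(E)
  if (nE < 100) .nf_error("lesion too small", "nf_calibration_error")
  k <- ceiling(0.05 * nE)
  floor_px <- spec$marker_intensity + 0.02

  # AF plane: affine shift/scale of a smooth texture; mean is exact.
  ta <- .smooth_field(nr, nc, spec$texture_spacing)[E]
  ta <- (ta - mean(ta)) / max(stats::sd(ta), 1e-12)
  s_af <- min(0.04,
              (targets$af - floor_px) / max(-min(ta), 1e-9),
              (0.97 - targets$af) / max(max(ta), 1e-9))
  s_af <- max(s_af, 0)
  af_px <- targets$af + s_af * ta

  # G plane: anchor the affine map at the min-5% mean so it is exact for
  # any spread; then derive the skin G base from the p-prime target.
  #
  # Both anchored statistics are lower-tail means, which additive noise
  # shifts down (the post-noise lowest 5% preferentially picks negative
  # noise). A constant shift commutes exactly with the min-5% operator,
  # so the anchors are corrected by the Monte-Carlo expectation of that
  # shift under the scene's noise sd: the drawn targets then equal the
  # *expected measured* statistics. With zero noise the correction
  # vanishes and the construction is exact pre-noise.
  fR <- if (neutral_r_ir) 1 else rnorm(1, 1, 0.02)
  fIR <- if (neutral_r_ir) 1 else rnorm(1, 1, 0.02)
  tg <- .smooth_field(nr, nc, spec$texture_spacing)[E]
  tg <- (tg - mean(tg)) / max(stats::sd(tg), 1e-12)
  ord_k <- order(tg)[seq_len(k)]
  mu5 <- mean(tg[ord_k])
  s_g <- max(0, min(0.05, (targets$gmin5 - floor_px) / max(mu5 - min(tg), 1e-9)))
  p_t <- targets$pmin5
  min5m <- function(v) mean(sort(v, partial = k)[seq_len(k)])
  n_rep <- if (spec$noise_sd > 0) 4L else 0L
  r_les <- fR * spec$skin_base[["R663"]]
  ir_les <- fIR * spec$skin_base[["IR964"]]
  for (it in 1:8) {
    g_px <- targets$gmin5 + s_g * (tg - mu5)
    # noise-tail correction for min-5% of G
    if (n_rep > 0) {
      d_g <- mean(vapply(seq_len(n_rep), function(i)
        min5m(g_px + rnorm(nE, 0, spec$noise_sd)), numeric(1))) - targets$gmin5
      g_px <- g_px - d_g
    }
    m <- mean(log10(pmax(g_px[ord_k], 1e-4)))
    if (!is.null(fixed_skin_g)) {
      gs <- fixed_skin_g
      if (targets$gmin5 >= gs)
        .nf_error("infeasible target: gmin5 >= skin G base", "nf_calibration_error")
      p_t <- m - log10(gs)
    } else {
      p_t <- targets$pmin5
      gs <- 10^(m - p_t)
      # noise-tail correction for min-5% of the p-prime map (G, R and IR
      # pixel noise all feed the map; a log-domain offset of the skin G
      # base commutes with its min-5%)
      if (n_rep > 0) {
        off <- log10(spec$skin_base[["R663"]] * spec$skin_base[["IR964"]] / gs)
        d_p <- mean(vapply(seq_len(n_rep), function(i) {
          pv <- log10(pmax(g_px + rnorm(nE, 0, spec$noise_sd), 1e-4)) -
            log10(pmax(r_les + rnorm(nE, 0, spec$noise_sd), 1e-4)) -
            log10(pmax(ir_les + rnorm(nE, 0, spec$noise_sd), 1e-4)) + off
          min5m(pv)
        }, numeric(1))) - p_t
        gs <- gs * 10^d_p
      }
      if (gs > 0.97) { gs <- 0.97; p_t <- m - log10(gs) }
    }
    if (max(g_px) <= gs - 0.03 || s_g <= 1e-8) break
    s_g <- if (s_g < 1e-4) 0 else s_g / 2
  }

  base <- spec$skin_base
  base[["G526"]] <- gs
  lesion_vals <- list(AF405 = af_px, G526 = g_px,
                      R663 = rep(fR * base[["R663"]], nE),
                      IR964 = rep(fIR * base[["IR964"]], nE))

  images <- list()
  for (b in spectral_bands()) {
    plane <- matrix(base[[b]], nr, nc)
    plane[E] <- lesion_vals[[b]]
    plane[M] <- spec$marker_intensity
    off <- spec$offsets[[b]]
    plane <- .shift_matrix(plane, off[1], off[2], fill = base[[b]])
    if (spec$noise_sd > 0)
      plane <- plane + rnorm(nr * nc, 0, spec$noise_sd)
    plane <- pmin(pmax(plane, 0), 1)
    arr <- array(0, c(nr, nc, 3))
    sig <- .band_channel[[b]]
    arr[, , sig] <- plane
    arr[, , setdiff(1:2, sig)] <- 0.5 * plane
    arr[, , 3] <- 0.2 * plane
    images[[b]] <- arr
  }

  truth <- list(
    lesion_mask = E, marker_mask = M, offsets = spec$offsets,
    targets_drawn = targets,
    targets_achieved = list(af = targets$af, gmin5 = targets$gmin5,
                            pmin5 = p_t),
    skin_base = base, r_ir_factors = c(R663 = fR, IR964 = fIR),
    lesion_spread_g = s_g)
  list(images = images, truth = truth)
}

#' Render a scene for one manifest entry (seeded)
#'
#' Seeds the RNG with the entry's scene seed, draws per-lesion targets for
#' its class, draws a random geometry and renders the scene. This is the
#' deterministic path used for seed-column manifests.
#'
#' @param class_label Lesion class.
#' @param scene_seed Integer seed for this scene.
#' @param size Image size `c(rows, cols)`.
#' @param ... Passed to [random_scene_spec()].
#' @return As [render_scene()].
#' @export
render_scene_from_seed <- function(class_label, scene_seed,
                                   size = c(512, 512), ...) {
  set.seed(as.integer(scene_seed))
  targets <- sample_lesion_targets(class_label, 1)
  spec <- random_scene_spec(size = size, ...)
  render_scene(spec, targets)
}

.cohort_presets <- list(
  nf1_2023 = c(cafe_au_lait = 25, neurofibroma = 65, dermatofibroma = 16,
               intradermal_nevus = 4, junctional_nevus = 129,
               lentigo_solaris = 17)
)

#' Render a synthetic cohort
#'
#' Generates a manifest (and optionally image files) for a cohort of
#' synthetic scenes. The `nf1_2023` preset reproduces the study cohort
#' composition: 25 cafe-au-lait macules and 65 neurofibromas (90
#' NF1-related datasets) vs 16 dermatofibromas, 4 intradermal nevi, 129
#' junctional nevi and 17 lentigines solaris (166 non-NF1 datasets).
#'
#' @param preset `"nf1_2023"` or `"custom"` (requires `n_per_class`).
#' @param seed Cohort seed; per-scene seeds are drawn from it.
#' @param n_per_class Named integer vector of scene counts per class
#'   (for `preset = "custom"`).
#' @param out_dir If non-NULL, write the manifest (and images if
#'   `write_images`) under this directory.
#' @param write_images Write per-band 16-bit RGB PNGs and ground-truth
#'   mask PNGs per scene (requires `out_dir`).
#' @param size Image size `c(rows, cols)`.
#' @param ... Passed to [random_scene_spec()] when rendering.
#' @return Manifest data frame (with `seed` column, and path columns if
#'   images were written), validated.
#' @export
render_cohort <- function(preset = c("nf1_2023", "custom"), seed = 1,
                          n_per_class = NULL, out_dir = NULL,
                          write_images = FALSE, size = c(512, 512), ...) {
  preset <- match.arg(preset)
  counts <- if (preset == "custom") {
    if (is.null(n_per_class))
      .nf_error("custom preset requires n_per_class", "nf_format_error")
    bad <- setdiff(names(n_per_class), lesion_classes())
    if (length(bad)) .nf_error(sprintf("unknown class: %s", bad[1]),
                               "nf_format_error")
    n_per_class[n_per_class > 0]
  } else .cohort_presets[[preset]]
  set.seed(as.integer(seed))
  classes <- rep(names(counts), counts)
  n <- length(classes)
  scene_seeds <- sample.int(2147483646L, n)
  manifest <- data.frame(
    lesion_id = sprintf("%s_%03d", classes,
                        unlist(lapply(counts, seq_len), use.names = FALSE)),
    class_label = classes,
    seed = scene_seeds,
    stringsAsFactors = FALSE)
  if (write_images) {
    if (is.null(out_dir))
      .nf_error("write_images requires out_dir", "nf_format_error")
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- matrix("", n, 4,
                    dimnames = list(NULL, .manifest_path_cols))
    for (i in seq_len(n)) {
      sc <- render_scene_from_seed(manifest$class_label[i],
                                   manifest$seed[i], size = size, ...)
      for (j in seq_along(spectral_bands())) {
        b <- spectral_bands()[j]
        p <- file.path(out_dir, sprintf("%s_%s.png", manifest$lesion_id[i], b))
        write_png16(sc$images[[b]], p)
        paths[i, j] <- p
      }
      write_mask_png(sc$truth$lesion_mask,
                     file.path(out_dir, sprintf("%s_lesion_mask.png",
                                                manifest$lesion_id[i])))
      write_mask_png(sc$truth$marker_mask,
                     file.path(out_dir, sprintf("%s_marker_mask.png",
                                                manifest$lesion_id[i])))
    }
    manifest <- cbind(manifest, as.data.frame(paths, stringsAsFactors = FALSE))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_manifest(manifest, file.path(out_dir, "manifest.csv"),
                   provenance = c(seed = seed, preset = preset,
                                  nfspectral = as.character(packageVersion("nfspectral"))))
  }
  validate_manifest(manifest)
}
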