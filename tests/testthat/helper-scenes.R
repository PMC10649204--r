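# Shared fixture builders. Test scenes are 192x192 with the generator's
# auto-scaled geometry (marker radius 9, lesion semi-axes 15-30 px),
# which keeps the darkness-quantile occupancy of the marker identical to
# full-size scenes (~72%) so detection behaves the same.

test_scene_size <- c(192, 192)

zero_offsets <- function() {
  list(AF405 = c(0, 0), G526 = c(0, 0), R663 = c(0, 0), IR964 = c(0, 0))
}

make_scene <- function(class_label = "cafe_au_lait", seed = 1,
                       size = test_scene_size, noise_sd = 0.01,
                       offsets = NULL, neutral_r_ir = FALSE,
                       targets = NULL, ...) {
  set.seed(seed)
  if (is.null(targets)) targets <- sample_lesion_targets(class_label, 1)
  spec <- random_scene_spec(size = size, noise_sd = noise_sd, ...)
  if (!is.null(offsets)) spec$offsets <- offsets
  render_scene(spec, targets, neutral_r_ir = neutral_r_ir)
}

# noise-free, offset-free scene: the exact-construction regime
make_clean_scene <- function(class_label = "cafe_au_lait", seed = 1,
                             neutral_r_ir = TRUE, targets = NULL) {
  make_scene(class_label, seed, noise_sd = 0, offsets = zero_offsets(),
             neutral_r_ir = neutral_r_ir, targets = targets)
}

scene_planes <- function(scene) {
  planes <- lapply(spectral_bands(), function(b)
    extract_channel(scene$images[[b]], b))
  names(planes) <- spectral_bands()
  planes
}

mask_iou <- function(a, b) sum(a & b) / sum(a | b)
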