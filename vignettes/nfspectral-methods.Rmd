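---
title: "Multispectral skin-lesion analysis: model, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multispectral skin-lesion analysis: model, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The measurement model

A handheld multispectral device images a skin lesion four times under
narrow-band LED illumination: 526 nm (green), 663 nm (red) and 964 nm
(near infrared) for diffuse reflectance, and 405 nm through a 515 nm
long-pass filter for autofluorescence (AF). Each acquisition is an RGB
frame; only one channel per frame carries the signal (G for the 526 nm
and AF images, R for the 663 and 964 nm images), and the blue channel is
never used. All intensities are normalized to $[0,1]$ "arbitrary units"
(a.u.) by dividing by the sensor bit-depth maximum; the pipeline assumes
uniform exposure and performs no white-reference calibration.

Reflectance at these wavelengths is modulated by the major skin
chromophores — hemoglobin (strongly absorbing near 526 nm), melanin
(broadband, decaying with wavelength) and water (near infrared) — so
intensity ratios between a lesion and its surrounding healthy skin carry
compositional information. The headline statistic is the per-pixel
chromophore-contrast parameter

$$
p' \;=\; \log_{10}
\frac{G_\text{lesion}\,\bar R_\text{skin}\,\overline{IR}_\text{skin}}
     {\bar G_\text{skin}\,R_\text{lesion}\,IR_\text{lesion}},
$$

computed for every lesion pixel against the *means* of the perilesional
skin pixels (bars). $p'$ is negative when the lesion absorbs more green
light than the surrounding skin relative to its red/infrared behaviour.
Because the skin terms renormalize each patient's baseline, $p'$ is
comparable across patients in a way the raw $G$ intensity is not.

Two aggregation choices deserve mention:

* **Per-pixel map, not scalar ratio.** $p'$ is evaluated per lesion
  pixel (a map), and "mean of $p'$" / "min-5% of $p'$" are statistics of
  that map. The min-5% statistic requires a distribution, so the
  per-pixel reading is the only self-consistent one.
* **Min-5% statistics.** For a region of $n$ pixels the min-5% mean is
  the mean of the $k=\lceil 0.05\,n\rceil$ smallest values (max-5%
  symmetric). Automatic lesion masks are imperfect and tend to admit
  *brighter* skin pixels; since skin is lighter than every lesion type
  imaged, the low tail is robust to that contamination. Variances are
  population variances (fixed for determinism; immaterial at lesion
  pixel counts).

All six factors of $p'$ are clamped below at $\varepsilon = 10^{-4}$
before the ratio, so underexposed pixels produce finite values; clamping
is counted and flagged in the output rather than silently absorbed.

## Preprocessing

**Marker detection.** A near-black circular fiducial marker is placed on
healthy skin next to the lesion before acquisition. Detection thresholds
the plane at its 0.5% intensity quantile, applies a 1 px morphological
closing (under noise, a random ~30% of marker pixels fall above the
quantile threshold, and closing keeps the marker a single component),
rejects components larger than 5% of the image (degenerate thresholds),
keeps the largest remaining component and fills its holes. The centroid
is the subpixel mean of member coordinates.

**Stabilization.** The four frames are acquired sequentially over
seconds with a handheld device, so inter-frame motion is dominantly
translational. Each plane is shifted by the integer-rounded difference
between its marker centroid and the reference band's (G526, the
segmentation band), then all planes are cropped to the common region. No
rotation or scale correction is attempted.

**Skin range.** The marker sits on healthy skin, so a skin sample is
read from an annulus around it: the marker mask dilated by twice its
equivalent radius, minus an inner guard zone (the mask dilated by 0.25
equivalent radii). The guard zone exists because the darkness threshold
under-covers the true marker by a noisy rim; without it those near-black
pixels inflate the annulus SD several-fold and destroy the threshold
below. The skin range is mean $\pm k\,$SD with $k=2$; a zero-variance
annulus is widened by 0.01 a.u. A band whose annulus SD exceeds three
times the across-band median SD is flagged (`annulus_inflated`) — the
signature of a marker placed close enough to the lesion that the annulus
clips it.

**Segmentation.** Lesion candidates are pixels darker than the lower
skin bound on the G526 plane (the band with the strongest lesion
contrast), excluding the dilated marker zone; the largest connected
component is kept, holes filled, and a 2 px opening removes speckle. The
resulting mask is reused for all four bands. When automatic segmentation
fails or is poor, an external 8-bit mask (e.g. drawn in an annotation
tool) overrides it; override pixel counts are preserved verbatim, and
the skin/marker masks yield where they overlap the override so the three
masks stay disjoint.

None of the numeric preprocessing constants (quantile 0.005, area cap
5%, dilation factor 2, guard 0.25, $k=2$, opening 2 px) is documented by
the acquisition study; they are package defaults surfaced in
`pipeline_config()`.

## Classification and evaluation

Evaluation is deliberately univariate: for each parameter (mean of
G(lesion), min-5% of G(lesion), mean of $p'$, min-5% of $p'$) and each
positive grouping (café-au-lait macules, neurofibromas, all NF1-related
lesions), a threshold is chosen to maximize Youden's
$J = \text{sensitivity} + \text{specificity} - 100$ against the *pooled*
non-NF1 group, ties broken toward higher sensitivity. The source study
does not state its threshold rule; maximizing $J$ on the pooled
comparison is adopted because each published row reports a single
sensitivity with per-class specificities, which is only coherent under
one shared threshold per row. Positives score *above* the threshold for
all four parameters (NF1-related lesions have higher $G$ and $p'$
statistics), though the direction is configurable. Sensitivity and
specificity are $100\,TP/(TP+FN)$ and $100\,TN/(TN+FP)$; confidence
intervals are Wilson score intervals (the study says only "95% CI"; the
Wilson interval is well-behaved at the small per-class counts, where
Wald intervals overshoot).

## The synthetic scene generator

No public imaging data exist for this device, so validation rests on a
synthetic world whose *cohort-level* pipeline outputs are calibrated to
the published per-class group statistics: mean AF(lesion), min-5% of
G(lesion), and min-5% of $p'$ — six classes, mean and SD each
(`class_calibrations()`).

A scene is: a flat skin background per band (AF 0.35, R663 0.70, IR964
0.65 a.u.; the G526 base is derived per scene, below), one elliptical
lesion (semi-axes 40–80 px at 512×512, random rotation), and a marker
disc (intensity 0.02 a.u.) at least 30 px from the lesion boundary.
Per-band integer translations are drawn uniformly from $[-5,5]$ px
(G526 fixed at zero as reference), then additive Gaussian noise
(sd 0.01 a.u.) is applied and values clipped to $[0,1]$. Geometry
defaults scale linearly with image size so smaller scenes behave
identically; in particular the ratio between the darkness-quantile pixel
count and the marker area (~72%) is size-invariant. The marker radius
default is 24 px: a 12 px marker (452 px area) would be *smaller* than
the 0.5% quantile count at 512×512 (1311 px), making the largest dark
component the lesion's low tail rather than the marker — detection would
fail by construction.

**Exact target construction.** Per lesion, targets
$(a, g_5, p_5)$ are drawn from independent Normals with the calibrated
class means/SDs and clamped to physically valid ranges (intensities in
$[0.05, 0.95{-}0.97]$ — every lesion pixel must stay above the marker
intensity — and $p_5 \in [-1.6, -0.02]$ so the lesion is darker than
skin at 526 nm). Clamping, rather than rejection-resampling, is used
because it distorts the cohort mean far less for classes whose printed
mean sits near the physical floor. Then:

1. AF lesion pixels are an affine map of a smooth random texture
   (coarse Gaussian noise, bilinearly upsampled) with mean exactly $a$.
2. G lesion pixels are an affine map of an independent texture
   *anchored at its min-5% mean*: $G = g_5 + s\,(t - \mu_5(t))$, which
   makes the min-5% mean equal $g_5$ exactly for any spread $s$; $s$ is
   shrunk as needed to respect the pixel floor and the skin contrast
   margin.
3. The G skin base is set to $G_s = 10^{m - p_5}$ where $m$ is the mean
   $\log_{10}$ of those same lowest-5% G pixels. With no R/IR lesion
   contrast the $p'$ map is a monotone transform of the G plane, so its
   lowest 5% are the same pixels and the min-5% of $p'$ equals $p_5$
   exactly before noise. ($G_s$ is capped at 0.97; the rare draws that
   hit the cap get a correspondingly adjusted $p_5$, recorded in the
   ground truth.)
4. R663/IR964 lesion pixels sit at the skin level times a scalar factor
   drawn from Normal(1, 0.02) per band — the published analysis found no
   significant lesion contrast in these bands.

The within-lesion texture (spacing 32 px, spread $\le$ 0.05 a.u.) is a
free modelling choice: the study reports no per-pixel distributions.

**Calibrating to the measurement operator.** Both anchored statistics
are *lower-tail means*, and additive pixel noise shifts the expected
post-noise lower tail down: the lowest 5% after noise preferentially
selects pixels with negative noise (for a noise-dominated region the
shift approaches $-2.06\,\sigma$, the mean of the lowest 5% of a
Gaussian). The published values are measurements on noisy images, so
anchoring pre-noise would make the full-pipeline cohort means
systematically low — by 0.01–0.07 in min-5% $p'$, outside Monte-Carlo
tolerance for every class. Because a constant (or log-domain constant)
shift commutes exactly with the min-5% operator, the renderer corrects
each anchor by the Monte-Carlo expectation of the noise-induced tail
shift (4 noise replicates drawn from the scene RNG, so scenes remain
bit-reproducible): the G pixels are shifted up by the expected G-tail
shift, and the skin G base absorbs the expected $p'$-map tail shift
(which also includes the R and IR pixel noise). The drawn target then
equals the *expected measured* statistic; at zero noise both corrections
vanish and the construction is exact pre-noise, so the exactness
invariants are unchanged.

**The manual-mask fallback.** The acquisition protocol reports that
automatic thresholding produced adequate segments in about 80% of cases,
with the remainder masked or corrected by hand. The synthetic world
reproduces both halves: when automatic segmentation fails (no pixels
below the skin range — draws with $p_5$ near $-0.02$ have almost no
lesion/skin contrast), cohort processing retries with the scene's
ground-truth mask standing in for the human annotation, flagged
`mask_source = "override"`. Fallback rates at default noise run 1.5%
(café-au-lait) to 12.5% (neurofibromas, the lowest-contrast class).
Without the fallback the failures — concentrated in high-$p_5$ draws —
select the surviving cohort and bias its min-5% $p'$ mean low, exactly
the selection effect the study avoided by hand-masking.

**What a green test establishes — and what it does not.** The generator
reproduces the *intensity structure* the pipeline exploits (dark marker,
light skin, darker lesion, weak R/IR contrast, inter-band jitter,
additive noise) and its cohort statistics are calibrated to the
published group values. It does not model optical tissue physics, camera
noise, hair, specular highlights, illumination gradients or soft lesion
borders. Green calibration-recovery tests therefore establish that the
*pipeline implementation* is faithful and unbiased under the stated
world — not that the device's clinical numbers are reproduced on real
skin. The published patient-level sensitivities/specificities (Table-3
analogues) are *not* reproducible from synthetic data; their qualitative
anchor — min-5% $p'$ is the best separator for neurofibromas, min-5% G
for café-au-lait macules — is asserted as a majority-of-seeds property
instead.

## Numerical and degenerate-input choices

* Thresholding quantiles use R's default (type 7) quantile —
  deterministic.
* Marker detection errors (`nf_marker_not_found`) when no component
  survives the area cap — e.g. a uniform image where the "dark" set
  spans everything.
* Segmentation errors (`nf_segmentation_failed`) when no pixel falls
  below the skin range — e.g. a lesion whose intensity lies inside the
  skin band. In cohort processing these trigger the manual-mask fallback
  (above) when a ground-truth or `mask_path` mask exists; otherwise the
  row is marked and logged, never fatal.
* Ties in Youden's $J$ break toward higher sensitivity; sweep thresholds
  are midpoints between adjacent distinct pooled values plus one
  sentinel beyond each extreme.
* Per-scene RNG seeds are drawn once from the cohort seed and stored in
  the manifest, so disk-based and in-memory processing are
  reproducible and identical up to 16-bit quantization.

## Known limitations

* Registration is integer-translation only; rotation, scale or
  deformable motion would need a richer model than the fiducial marker
  supports.
* The skin estimate comes from a single annulus; a strongly textured or
  vignetted background would bias it (flagged, not corrected).
* The independent-Normal target model can draw jointly implausible
  combinations (e.g. a very dark lesion with mild $p'$), producing
  near-black synthetic "skin"; these scenes usually fail automatic
  segmentation and are handled by the mask fallback.
* Min-5% statistics are robust to bright contamination but sensitive to
  *dark* artifacts (hair, shadows), which the generator does not model.
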