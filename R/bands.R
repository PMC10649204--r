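#' Spectral bands of a multispectral dataset
#'
#' One dataset holds four RGB images taken under: 405 nm LEDs through a
#' 515 nm long-pass filter (autofluorescence, `AF405`), and 526 nm
#' (`G526`), 663 nm (`R663`) and 964 nm (`IR964`) narrow-band LEDs
#' (diffuse reflectance).
#'
#' @return Character vector of the four band labels, in canonical order.
#' @export
spectral_bands <- function() c("AF405", "G526", "R663", "IR964")

# RGB channel index carrying the signal of each band. Reflectance at
# 526 nm is read from the G channel, 663 and 964 nm from the R channel;
# the autofluorescence image also uses the G channel (the most informative
# part of the autofluorescence signal). The B channel is never used.
.band_channel <- c(AF405 = 2L, G526 = 2L, R663 = 1L, IR964 = 1L)

.check_band <- function(band) {
  if (length(band) != 1 || !band %in% spectral_bands())
    .nf_error(sprintf("unknown band '%s' (expected one of %s)",
                      paste(band, collapse = ","),
                      paste(spectral_bands(), collapse = ", ")),
              "nf_format_error")
  band
}

#' Extract the informative channel of a band image
#'
#' Maps each illumination band to the RGB channel that carries its signal:
#' `AF405` and `G526` use the green channel, `R663` and `IR964` the red
#' channel. Values are returned untouched.
#'
#' @param image Height x width x 3 numeric array in `[0, 1]`
#'   (see [read_rgb_image()]).
#' @param band Band label, one of [spectral_bands()].
#' @return Numeric matrix (the channel plane) with attribute `band`.
#' @export
extract_channel <- function(image, band) {
  .check_band(band)
  d <- dim(image)
  if (is.null(d) || length(d) != 3 || d[3] < 3)
    .nf_error("image must be a height x width x 3 array", "nf_format_error")
  plane <- matrix(image[, , .band_channel[[band]]], d[1], d[2])
  structure(plane, band = band)
}

#' Assemble a multispectral set from four RGB band images
#'
#' @param images Named list with one RGB array per band label.
#' @param lesion_id Identifier for the lesion.
#' @return A `multispectral_set`: list with `planes` (named list of
#'   matrices), `lesion_id` and `aligned = FALSE`.
#' @export
multispectral_set <- function(images, lesion_id = "lesion") {
  if (!all(spectral_bands() %in% names(images)))
    .nf_error("images must be a named list covering all four bands",
              "nf_format_error")
  planes <- lapply(spectral_bands(), function(b) extract_channel(images[[b]], b))
  names(planes) <- spectral_bands()
  structure(list(planes = planes, lesion_id = lesion_id, aligned = FALSE),
            class = "multispectral_set")
}

#' @export
print.multispectral_set <- function(x, ...) {
  d <- dim(x$planes[[1]])
  cat(sprintf("multispectral_set '%s': %d x %d, %s\n", x$lesion_id,
              d[1], d[2], if (x$aligned) "aligned" else "raw"))
  invisible(x)
}
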