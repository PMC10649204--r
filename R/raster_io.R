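# Raster IO: PNG (8/16-bit, via png::readPNG for reading; own 16-bit
# writer since png 0.1-8 writes 8-bit only) and minimal uncompressed TIFF
# (8/16-bit gray/RGB, float32 for parameter-map export).

.u32be <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %/% 16777216, (x %/% 65536) %% 256, (x %/% 256) %% 256, x %% 256))
}

.png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  crc <- .crc32_raw(body, 0)
  c(.u32be(length(data)), body, .u32be(crc))
}

# PNG IDAT requires a zlib stream. R's memCompress(type = "gzip")
# actually emits zlib (0x78 header) on this platform, which can be used
# directly; if a build ever emits a true gzip container, re-wrap its
# deflate payload with a zlib header and Adler-32 trailer.
.zlib_wrap <- function(raw_data) {
  gz <- memCompress(raw_data, type = "gzip")
  if (gz[1] == as.raw(0x78)) return(gz)
  flg <- as.integer(gz[4])
  off <- 10L
  if (bitwAnd(flg, 4L) > 0) { # FEXTRA
    xlen <- as.integer(gz[off + 1L]) + 256L * as.integer(gz[off + 2L])
    off <- off + 2L + xlen
  }
  if (bitwAnd(flg, 8L) > 0) { # FNAME, zero-terminated
    while (gz[off + 1L] != as.raw(0)) off <- off + 1L
    off <- off + 1L
  }
  if (bitwAnd(flg, 16L) > 0) { # FCOMMENT
    while (gz[off + 1L] != as.raw(0)) off <- off + 1L
    off <- off + 1L
  }
  if (bitwAnd(flg, 2L) > 0) off <- off + 2L # FHCRC
  deflate <- gz[(off + 1L):(length(gz) - 8L)]
  adler <- .adler32_raw(raw_data)
  c(as.raw(c(0x78, 0x9c)), deflate, .u32be(adler))
}

#' Write a 16-bit PNG image
#'
#' Writes a grayscale matrix or an RGB array of intensities in `[0, 1]` as a
#' 16-bit PNG (the raw storage format of the synthetic scene generator).
#'
#' @param pixels Numeric matrix (grayscale) or height x width x 3 array
#'   (RGB) with values in `[0, 1]`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_png16 <- function(pixels, path) {
  if (is.matrix(pixels)) {
    h <- nrow(pixels); w <- ncol(pixels); nch <- 1L; color_type <- 0L
    chans <- list(pixels)
  } else if (is.array(pixels) && length(dim(pixels)) == 3 && dim(pixels)[3] == 3) {
    h <- dim(pixels)[1]; w <- dim(pixels)[2]; nch <- 3L; color_type <- 2L
    chans <- lapply(1:3, function(k) pixels[, , k])
  } else {
    .nf_error("pixels must be a matrix or an h x w x 3 array", "nf_format_error")
  }
  ints <- lapply(chans, function(m) {
    round(pmin(pmax(m, 0), 1) * 65535)
  })
  # scanlines: filter byte 0, then big-endian 16-bit samples interleaved by
  # channel, pixels left-to-right, rows top-to-bottom
  bpr <- 2L * nch * w
  S <- matrix(0, nrow = bpr + 1L, ncol = h)
  for (k in seq_len(nch)) {
    tm <- t(ints[[k]]) # w x h
    hi <- tm %/% 256; lo <- tm %% 256
    pos <- 1L + (seq_len(w) - 1L) * 2L * nch + (k - 1L) * 2L
    S[pos + 1L, ] <- hi
    S[pos + 2L, ] <- lo
  }
  raw_scan <- as.raw(as.integer(S))
  ihdr <- c(.u32be(w), .u32be(h), as.raw(c(16L, color_type, 0L, 0L, 0L)))
  out <- c(
    as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
    .png_chunk("IHDR", ihdr),
    .png_chunk("IDAT", .zlib_wrap(raw_scan)),
    .png_chunk("IEND", raw())
  )
  writeBin(out, path)
  invisible(path)
}

#' Write an 8-bit binary mask as PNG
#'
#' @param mask Logical matrix; `TRUE` pixels are written as 255.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(ifelse(mask, 1, 0), path)
  invisible(path)
}

.png_bit_depth <- function(path) {
  hdr <- readBin(path, "raw", n = 26L)
  if (length(hdr) < 26L ||
      !identical(as.integer(hdr[1:8]), c(137L, 80L, 78L, 71L, 13L, 10L, 26L, 10L)))
    return(NA_integer_)
  as.integer(hdr[25])
}

#' Read an RGB image from PNG or TIFF
#'
#' Reads an 8- or 16-bit, 3-channel raster and scales intensities to
#' `[0, 1]` by dividing by the bit-depth maximum (255 or 65535).
#'
#' @param path Path to a PNG or TIFF file.
#' @return Height x width x 3 numeric array with values in `[0, 1]` and an
#'   attribute `bit_depth_source` (8 or 16).
#' @export
read_rgb_image <- function(path) {
  if (!file.exists(path))
    .nf_error(sprintf("image file not found: %s", path), "nf_io_error")
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    img <- read_tiff(path)
    depth <- attr(img, "bit_depth_source")
  } else {
    img <- png::readPNG(path) # already divided by bit-depth max
    depth <- .png_bit_depth(path)
  }
  d <- dim(img)
  if (length(d) != 3 || d[3] < 3)
    .nf_error(sprintf("expected a 3-channel image, got dims %s",
                      paste(d, collapse = "x")), "nf_format_error")
  if (d[3] > 3) img <- img[, , 1:3, drop = FALSE] # drop alpha
  structure(img, bit_depth_source = depth)
}

#' Read a single-channel raster (PNG or TIFF)
#'
#' @param path Path to the file.
#' @return Numeric matrix in `[0, 1]`.
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path))
    .nf_error(sprintf("image file not found: %s", path), "nf_io_error")
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) read_tiff(path) else png::readPNG(path)
  if (!is.matrix(img)) {
    if (length(dim(img)) == 3) img <- img[, , 1] else
      .nf_error("expected a single-channel image", "nf_format_error")
  }
  img
}

# --- minimal uncompressed TIFF (little-endian, single strip) ---

.tiff_entry <- function(tag, type, count, value) {
  sz <- c(`1` = 1L, `3` = 2L, `4` = 4L)[as.character(type)]
  con <- raw(12)
  con[1:2] <- writeBin(as.integer(tag), raw(), size = 2, endian = "little")
  con[3:4] <- writeBin(as.integer(type), raw(), size = 2, endian = "little")
  con[5:8] <- writeBin(as.integer(count), raw(), size = 4, endian = "little")
  vraw <- if (type == 3L) {
    unlist(lapply(value, function(v) writeBin(as.integer(v), raw(), size = 2, endian = "little")))
  } else {
    unlist(lapply(value, function(v) writeBin(as.integer(v), raw(), size = 4, endian = "little")))
  }
  stopifnot(length(vraw) <= 4) # offsets to external values handled by caller
  con[9:(8 + length(vraw))] <- vraw
  con
}

#' Write a grayscale or RGB TIFF (uncompressed)
#'
#' Supports 8- and 16-bit unsigned integer data, and 32-bit float for
#' signed parameter maps (e.g. p-prime maps).
#'
#' @param pixels Matrix (gray) or h x w x 3 array (RGB). For integer
#'   formats values must be in `[0, 1]`; for `float` they are written as-is.
#' @param path Output file path.
#' @param bits One of 8, 16, or 32 (32 implies float sample format).
#' @return `path`, invisibly.
#' @export
write_tiff <- function(pixels, path, bits = 16) {
  if (is.matrix(pixels)) {
    h <- nrow(pixels); w <- ncol(pixels); spp <- 1L; photometric <- 1L
    chans <- list(pixels)
  } else if (is.array(pixels) && length(dim(pixels)) == 3 && dim(pixels)[3] == 3) {
    h <- dim(pixels)[1]; w <- dim(pixels)[2]; spp <- 3L; photometric <- 2L
    chans <- lapply(1:3, function(k) pixels[, , k])
  } else .nf_error("pixels must be a matrix or an h x w x 3 array", "nf_format_error")
  float_fmt <- bits == 32
  # interleave channels pixel-by-pixel, row-major
  inter <- matrix(0, nrow = spp * w, ncol = h)
  for (k in seq_len(spp)) inter[seq(k, spp * w, by = spp), ] <- t(chans[[k]])
  vals <- as.vector(inter)
  data_raw <- if (float_fmt) {
    writeBin(as.numeric(vals), raw(), size = 4, endian = "little")
  } else {
    mx <- 2^bits - 1
    writeBin(as.integer(round(pmin(pmax(vals, 0), 1) * mx)), raw(),
             size = bits / 8, endian = "little")
  }
  n_entries <- 10L
  ifd_offset <- 8L
  data_offset <- ifd_offset + 2L + n_entries * 12L + 4L
  bits_vec <- rep(as.integer(bits), spp)
  # BitsPerSample for RGB needs 3 shorts (6 bytes) -> external value
  ext <- raw(0)
  if (spp == 3L) {
    bps_value_offset <- data_offset
    ext <- unlist(lapply(bits_vec, function(v)
      writeBin(as.integer(v), raw(), size = 2, endian = "little")))
    data_offset <- data_offset + length(ext)
  }
  entries <- c(
    .tiff_entry(256, 4L, 1L, w),                       # ImageWidth
    .tiff_entry(257, 4L, 1L, h),                       # ImageLength
    if (spp == 1L) .tiff_entry(258, 3L, 1L, bits) else {
      e <- .tiff_entry(258, 3L, 3L, 0L)
      e[9:12] <- writeBin(as.integer(bps_value_offset), raw(), size = 4, endian = "little")
      e
    },
    .tiff_entry(259, 3L, 1L, 1L),                      # Compression: none
    .tiff_entry(262, 3L, 1L, photometric),             # Photometric
    .tiff_entry(273, 4L, 1L, data_offset),             # StripOffsets
    .tiff_entry(277, 3L, 1L, spp),                     # SamplesPerPixel
    .tiff_entry(278, 4L, 1L, h),                       # RowsPerStrip
    .tiff_entry(279, 4L, 1L, length(data_raw)),        # StripByteCounts
    .tiff_entry(339, 3L, 1L, if (float_fmt) 3L else 1L) # SampleFormat
  )
  out <- c(
    as.raw(c(0x49, 0x49)), writeBin(42L, raw(), size = 2, endian = "little"),
    writeBin(ifd_offset, raw(), size = 4, endian = "little"),
    writeBin(n_entries, raw(), size = 2, endian = "little"),
    entries,
    writeBin(0L, raw(), size = 4, endian = "little"),
    ext,
    data_raw
  )
  writeBin(out, path)
  invisible(path)
}

.tiff_read_u <- function(raw, off, size) {
  # little-endian unsigned integer at 0-based offset
  b <- as.integer(raw[(off + 1):(off + size)])
  sum(b * 256^(seq_len(size) - 1))
}

#' Read an uncompressed TIFF written by [write_tiff()]
#'
#' @param path Path to the file.
#' @return Matrix (gray) or h x w x 3 array (RGB), with attribute
#'   `bit_depth_source`. Integer data are scaled to `[0, 1]`; float data
#'   are returned as stored.
#' @export
read_tiff <- function(path) {
  rawv <- readBin(path, "raw", n = file.info(path)$size)
  if (length(rawv) < 8 || !(rawv[1] == as.raw(0x49) && rawv[2] == as.raw(0x49)))
    .nf_error("not a little-endian TIFF", "nf_format_error")
  ifd <- .tiff_read_u(rawv, 4, 4)
  n <- .tiff_read_u(rawv, ifd, 2)
  tags <- list()
  for (i in seq_len(n)) {
    e <- ifd + 2 + (i - 1) * 12
    tag <- .tiff_read_u(rawv, e, 2)
    type <- .tiff_read_u(rawv, e + 2, 2)
    cnt <- .tiff_read_u(rawv, e + 4, 4)
    vsz <- c(`1` = 1, `3` = 2, `4` = 4)[as.character(type)]
    if (is.na(vsz)) next
    if (cnt * vsz <= 4) {
      vals <- vapply(seq_len(cnt), function(j)
        .tiff_read_u(rawv, e + 8 + (j - 1) * vsz, vsz), numeric(1))
    } else {
      voff <- .tiff_read_u(rawv, e + 8, 4)
      vals <- vapply(seq_len(cnt), function(j)
        .tiff_read_u(rawv, voff + (j - 1) * vsz, vsz), numeric(1))
    }
    tags[[as.character(tag)]] <- vals
  }
  w <- tags[["256"]][1]; h <- tags[["257"]][1]
  bits <- tags[["258"]][1]
  spp <- if (is.null(tags[["277"]])) 1 else tags[["277"]][1]
  comp <- if (is.null(tags[["259"]])) 1 else tags[["259"]][1]
  fmt <- if (is.null(tags[["339"]])) 1 else tags[["339"]][1]
  if (comp != 1) .nf_error("only uncompressed TIFF is supported", "nf_format_error")
  off <- tags[["273"]][1]
  nvals <- w * h * spp
  con <- rawConnection(rawv[(off + 1):length(rawv)])
  on.exit(close(con))
  vals <- if (fmt == 3) {
    readBin(con, "numeric", n = nvals, size = 4, endian = "little")
  } else {
    v <- readBin(con, "integer", n = nvals, size = bits / 8,
                 endian = "little", signed = bits == 32)
    if (bits == 16) v[v < 0] <- v[v < 0] + 65536
    v / (2^bits - 1)
  }
  if (spp == 1) {
    out <- matrix(vals, nrow = h, ncol = w, byrow = TRUE)
  } else {
    out <- array(0, c(h, w, spp))
    for (k in seq_len(spp)) {
      out[, , k] <- matrix(vals[seq(k, nvals, by = spp)], nrow = h, ncol = w,
                           byrow = TRUE)
    }
  }
  structure(out, bit_depth_source = if (fmt == 3) 32L else as.integer(bits))
}
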