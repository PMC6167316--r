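#' Read a calibrated image
#'
#' Reads a TIFF or PNG image and attaches a pixel calibration.  For TIFF,
#' the resolution metadata is honoured when present: resolution in
#' pixels/inch or pixels/cm is converted to um/px, and resolution with
#' unit "none" follows the ImageJ micron convention (pixels per um).  When
#' no usable metadata exists, `pixel_size_um` must be supplied.  PNG
#' carries no physical calibration so always requires `pixel_size_um`.
#'
#' Intensities are returned on their native integer scale (0--255 for
#' 8-bit, 0--65535 for 16-bit).  An alpha channel, if present, is dropped
#' with a warning.  Anisotropic resolution metadata is an error.
#'
#' @param path TIFF (`.tif`/`.tiff`) or PNG file path.
#' @param pixel_size_um Fallback pixel size in um/px used when the file
#'   carries no resolution metadata.
#' @return A [calibrated_image()].
#' @seealso [write_image()]
#' @export
read_image <- function(path, pixel_size_um = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    px <- tiff::readTIFF(path, info = TRUE, as.is = FALSE)
    info <- attributes(px)
    bits <- as.integer(info$bits.per.sample %||% 8L)
    cal <- tiff_resolution_to_um(info)
  } else if (ext == "png") {
    px <- png::readPNG(path, info = TRUE)
    pinfo <- attr(px, "info")
    bits <- as.integer((pinfo$bit.depth %||% 8L))
    cal <- NULL
  } else {
    stop("unsupported image format: .", ext, " (use TIFF or PNG)",
         call. = FALSE)
  }
  if (!bits %in% c(8L, 16L))
    stop("unsupported bit depth: ", bits, " (8 or 16 expected)",
         call. = FALSE)
  if (is.null(cal)) {
    if (is.null(pixel_size_um))
      stop("no calibration: image carries no resolution metadata and no ",
           "pixel_size_um override was given", call. = FALSE)
    cal <- px_size(pixel_size_um)
  }
  nd <- length(dim(px))
  if (nd == 3L) {
    nch <- dim(px)[3]
    if (nch == 4L) {
      warning("alpha channel dropped")
      px <- px[, , 1:3, drop = FALSE]
    } else if (nch == 2L) {
      warning("gray+alpha image: alpha channel dropped")
      px <- px[, , 1, drop = TRUE]
    } else if (nch == 1L) {
      px <- px[, , 1, drop = TRUE]
    } else if (nch != 3L) {
      stop("unsupported channel count: ", nch, call. = FALSE)
    }
  }
  if (length(dim(px)) == 3L && bits != 8L)
    stop("RGB images must be 8-bit per channel", call. = FALSE)
  maxval <- 2^bits - 1
  vals <- round(unclass(as.vector(px)) * maxval)
  storage <- if (length(dim(px)) == 3L) array(vals, dim(px)) else
    matrix(vals, nrow(px), ncol(px))
  calibrated_image(storage, cal, bit_depth = bits)
}

# Convert tiff::readTIFF info attributes to um/px, or NULL when absent.
tiff_resolution_to_um <- function(info) {
  xr <- info$x.resolution
  yr <- info$y.resolution
  if (is.null(xr) || !is.finite(xr) || xr <= 0) return(NULL)
  if (!is.null(yr) && is.finite(yr) && yr > 0 &&
      abs(xr - yr) > 1e-6 * max(xr, yr))
    stop("anisotropic pixels are not supported (x and y resolution differ)",
         call. = FALSE)
  unit <- info$resolution.unit %||% "none"
  if (is.numeric(unit))
    unit <- c("none", "inch", "cm")[match(unit, c(1, 2, 3))] %||% "none"
  ps <- switch(as.character(unit),
               inch = 25400 / xr,
               cm   = 10000 / xr,
               1 / xr)  # unit "none": pixels per micron (ImageJ convention)
  # the TIFF reader reports resolution in single precision; snap to its
  # 7 significant digits so decimal calibrations round-trip exactly
  signif(ps, 7)
}

#' Write a calibrated image
#'
#' TIFF output embeds the pixel size as resolution metadata (pixels per
#' micron, resolution unit "none", ImageJ micron convention) in a baseline
#' uncompressed little-endian TIFF, so [read_image()] recovers both pixels
#' and calibration.  PNG output stores pixels only; the calibration must
#' travel separately.
#'
#' @param image A [calibrated_image()].
#' @param path Output path ending in `.tif`/`.tiff` or `.png`.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(is_calibrated_image(image))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    write_baseline_tiff(image, path)
  } else if (ext == "png") {
    if (image$bit_depth != 8L)
      stop("PNG output is 8-bit; use TIFF for 16-bit images",
           call. = FALSE)
    png::writePNG(image$pixels / 255, path)
  } else {
    stop("unsupported output format: .", ext, call. = FALSE)
  }
  invisible(path)
}

# Baseline TIFF writer (little-endian, single strip, uncompressed) with
# XResolution/YResolution/ResolutionUnit tags, which tiff::writeTIFF
# cannot emit.  Supports 8/16-bit grayscale and 8-bit RGB.
write_baseline_tiff <- function(image, path) {
  px <- image$pixels
  h <- dim(px)[1]; w <- dim(px)[2]
  spp <- image$channels
  bits <- image$bit_depth
  ps <- image$pixel_size_um

  # pixel data in TIFF order: rows top-to-bottom, samples interleaved
  if (spp == 1L) {
    vals <- as.integer(round(t(px)))
  } else {
    vals <- as.integer(round(aperm(px, c(3, 2, 1))))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  u16 <- function(x) writeBin(as.integer(x), con, size = 2,
                              endian = "little")
  u32 <- function(x) writeBin(as.integer(x), con, size = 4,
                              endian = "little")
  # header
  writeBin(charToRaw("II"), con); u16(42)
  data_len <- length(vals) * (bits / 8)
  desc <- "tailquant\nunit=micron\n"
  desc_len <- nchar(desc) + 1L                 # NUL-terminated
  strip_off <- 8L
  off <- strip_off + data_len
  bps_off <- off; if (spp == 3L) off <- off + 6L
  xres_off <- off; off <- off + 8L
  yres_off <- off; off <- off + 8L
  desc_off <- off; off <- off + desc_len
  if (off %% 2 == 1) { pad <- TRUE; off <- off + 1L } else pad <- FALSE
  ifd_off <- off
  u32(ifd_off)
  # strip
  if (bits == 8L) {
    writeBin(as.raw(vals), con)
  } else {
    writeBin(vals, con, size = 2, endian = "little")
  }
  # out-of-line values
  if (spp == 3L) u16(c(bits, bits, bits))
  # XResolution = pixels per micron as a rational num/den; den encodes
  # the pixel size so decimal calibrations are represented exactly
  den <- round(ps * 1e7)
  if (den < 1 || den > .Machine$integer.max)
    stop("pixel size out of encodable range for TIFF resolution",
         call. = FALSE)
  u32(c(1e7, den))   # XResolution
  u32(c(1e7, den))   # YResolution
  writeBin(c(charToRaw(desc), as.raw(0L)), con)
  if (pad) writeBin(as.raw(0L), con)
  # IFD
  entry <- function(tag, type, count, value, inline_short = FALSE) {
    u16(tag); u16(type); u32(count)
    if (inline_short) { u16(value); u16(0L) } else u32(value)
  }
  u16(13L)  # entry count
  entry(256, 4, 1, w)                                   # ImageWidth
  entry(257, 4, 1, h)                                   # ImageLength
  if (spp == 1L) entry(258, 3, 1, bits, inline_short = TRUE)
  else entry(258, 3, 3, bps_off)                        # BitsPerSample
  entry(259, 3, 1, 1, inline_short = TRUE)              # Compression
  entry(262, 3, 1, if (spp == 3L) 2 else 1,
        inline_short = TRUE)                            # Photometric
  entry(270, 2, desc_len, desc_off)                     # ImageDescription
  entry(273, 4, 1, strip_off)                           # StripOffsets
  entry(277, 3, 1, spp, inline_short = TRUE)            # SamplesPerPixel
  entry(278, 4, 1, h)                                   # RowsPerStrip
  entry(279, 4, 1, data_len)                            # StripByteCounts
  entry(282, 5, 1, xres_off)                            # XResolution
  entry(283, 5, 1, yres_off)                            # YResolution
  entry(296, 3, 1, 1, inline_short = TRUE)              # ResolutionUnit
  u32(0L)  # no next IFD
  invisible(path)
}
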