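#' Pixel calibration
#'
#' An isotropic pixel size in micrometres per pixel.  Every physical
#' measurement in the package (distances, areas, curvature radii) is
#' converted through this single scalar, e.g. the 50 um wound band and
#' the 50 um^2 mitotic-spot size filter.  Anisotropic calibrations are
#' rejected at image-reading time rather than averaged.
#'
#' @param pixel_size_um Micrometres per pixel; a single finite value > 0.
#' @return A `pixel_calibration` object.
#' @examples
#' pixel_calibration(0.65)
#' @export
pixel_calibration <- function(pixel_size_um) {
  if (inherits(pixel_size_um, "pixel_calibration")) return(pixel_size_um)
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("pixel_size_um must be a single finite value > 0", call. = FALSE)
  structure(list(pixel_size_um = as.numeric(pixel_size_um)),
            class = "pixel_calibration")
}

#' @export
print.pixel_calibration <- function(x, ...) {
  cat(sprintf("<pixel_calibration> %g um/px\n", x$pixel_size_um))
  invisible(x)
}

# Accept a pixel_calibration, a calibrated_image or a bare number and
# return the scalar pixel size in um.
px_size <- function(calibration) {
  if (inherits(calibration, "calibrated_image"))
    return(calibration$pixel_size_um)
  if (inherits(calibration, "pixel_calibration"))
    return(calibration$pixel_size_um)
  pixel_calibration(calibration)$pixel_size_um
}

#' Calibrated image
#'
#' A 2-D raster together with its isotropic pixel size.  Grayscale images
#' are numeric matrices (8- or 16-bit intensity scale, i.e. 0--255 or
#' 0--65535); RGB images are `height x width x 3` arrays on the 0--255
#' scale.  Images are assumed oriented anterior-left / dorsal-up.
#'
#' @param pixels Numeric matrix (grayscale) or `h x w x 3` array (RGB).
#' @param pixel_size_um Pixel size in um/px (or a [pixel_calibration()]).
#' @param bit_depth Intensity bit depth, 8 or 16 (RGB must be 8).
#' @return A `calibrated_image` object with fields `pixels`,
#'   `pixel_size_um`, `bit_depth`, `orientation`.
#' @examples
#' img <- calibrated_image(matrix(0, 10, 20), pixel_size_um = 1)
#' dim(img$pixels)
#' @export
calibrated_image <- function(pixels, pixel_size_um, bit_depth = 8L) {
  nd <- length(dim(pixels))
  if (nd == 2L) {
    channels <- 1L
  } else if (nd == 3L && dim(pixels)[3] == 3L) {
    channels <- 3L
  } else {
    stop("pixels must be a matrix or an h x w x 3 array", call. = FALSE)
  }
  if (!bit_depth %in% c(8L, 16L))
    stop("bit_depth must be 8 or 16", call. = FALSE)
  if (channels == 3L && bit_depth != 8L)
    stop("RGB images must be 8-bit per channel", call. = FALSE)
  if (any(dim(pixels)[1:2] < 1L))
    stop("image must be at least 1 x 1", call. = FALSE)
  maxval <- 2^bit_depth - 1
  rng <- range(pixels)
  if (!all(is.finite(rng)) || rng[1] < 0 || rng[2] > maxval)
    stop(sprintf("pixel intensities must lie in [0, %d]", maxval),
         call. = FALSE)
  structure(
    list(pixels = pixels,
         pixel_size_um = px_size(pixel_size_um),
         bit_depth = as.integer(bit_depth),
         channels = channels,
         orientation = "anterior-left"),
    class = "calibrated_image")
}

#' @export
print.calibrated_image <- function(x, ...) {
  cat(sprintf("<calibrated_image> %d x %d px, %s, %d-bit, %g um/px\n",
              ncol(x$pixels), nrow(x$pixels),
              if (x$channels == 3L) "RGB" else "grayscale",
              x$bit_depth, x$pixel_size_um))
  invisible(x)
}

#' @rdname calibrated_image
#' @param x Object to test.
#' @export
is_calibrated_image <- function(x) inherits(x, "calibrated_image")

# Image dimensions as c(height, width) regardless of channel count.
img_dim <- function(image) dim(image$pixels)[1:2]

#' Tidy measurement table
#'
#' Long-format results: one row per measurement per image, matching the
#' CSV the pipeline exports for downstream statistics.
#'
#' @param image_id Character vector of image identifiers.
#' @param measurement Measurement names.
#' @param value Numeric values.
#' @param units Units strings (non-empty), e.g. `"um"`, `"um2"`, `"count"`.
#' @return A data.frame with columns `image_id`, `measurement`, `value`,
#'   `units`.
#' @examples
#' result_table("fish01", "tail_length", 812.5, "um")
#' @export
result_table <- function(image_id = character(), measurement = character(),
                         value = numeric(), units = character()) {
  df <- data.frame(image_id = as.character(image_id),
                   measurement = as.character(measurement),
                   value = as.numeric(value),
                   units = as.character(units),
                   stringsAsFactors = FALSE)
  if (nrow(df) > 0 && any(!nzchar(df$units)))
    stop("units must be non-empty", call. = FALSE)
  if (anyDuplicated(df[c("image_id", "measurement")]))
    stop("one row per measurement per image", call. = FALSE)
  df
}

#' Read and write result tables
#'
#' @param results A result table (see [result_table()]).
#' @param path CSV file path.
#' @return `write_results` returns `path` invisibly; `read_results`
#'   returns the result table.
#' @export
write_results <- function(results, path) {
  stopifnot(all(c("image_id", "measurement", "value", "units") %in%
                  names(results)))
  utils::write.csv(results, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  result_table(df$image_id, df$measurement, df$value, df$units)
}

#' Read and write landmark / ROI point lists
#'
#' Landmarks and polygon ROIs are stored as CSV with header `name,x,y`;
#' coordinates are 0-based pixel units (sub-pixel values allowed).
#' Polygons are ordered rows sharing a `name`.
#'
#' @param path CSV file path.
#' @param landmarks A data.frame with columns `name`, `x`, `y`.
#' @return A data.frame with columns `name`, `x`, `y`.
#' @export
read_landmarks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("name", "x", "y") %in% names(df)))
    stop("landmark CSV must have columns name,x,y", call. = FALSE)
  if (!all(is.finite(df$x)) || !all(is.finite(df$y)))
    stop("landmark coordinates must be finite", call. = FALSE)
  df[c("name", "x", "y")]
}

#' @rdname read_landmarks
#' @export
write_landmarks <- function(landmarks, path) {
  stopifnot(all(c("name", "x", "y") %in% names(landmarks)))
  utils::write.csv(landmarks[c("name", "x", "y")], path, row.names = FALSE)
  invisible(path)
}
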