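#' RGB threshold
#'
#' Per-channel intensity windows defining the stain colour class: a
#' pixel is selected iff its red, green and blue values each fall inside
#' the corresponding `[min, max]` window, bounds inclusive.  Windows are
#' calibrated once per staining experiment (enzymatic staining intensity
#' varies between experiments) and then held constant across every image
#' of the batch so areas remain comparable.
#'
#' @param r_min,r_max,g_min,g_max,b_min,b_max Channel bounds in
#'   `[0, 255]`, `min <= max` per channel.
#' @return An `rgb_threshold` object.
#' @examples
#' blue <- rgb_threshold(0, 80, 0, 80, 120, 255)
#' @export
rgb_threshold <- function(r_min, r_max, g_min, g_max, b_min, b_max) {
  v <- c(r_min, r_max, g_min, g_max, b_min, b_max)
  if (length(v) != 6L || !all(is.finite(v)) || any(v < 0) || any(v > 255))
    stop("threshold bounds must lie in [0, 255]", call. = FALSE)
  if (r_min > r_max || g_min > g_max || b_min > b_max)
    stop("each channel window needs min <= max", call. = FALSE)
  structure(list(r = c(r_min, r_max), g = c(g_min, g_max),
                 b = c(b_min, b_max)),
            class = "rgb_threshold")
}

#' @export
print.rgb_threshold <- function(x, ...) {
  cat(sprintf("<rgb_threshold> R [%g, %g]  G [%g, %g]  B [%g, %g]\n",
              x$r[1], x$r[2], x$g[1], x$g[2], x$b[1], x$b[2]))
  invisible(x)
}

#' Select pixels inside an RGB threshold
#'
#' @param image A 3-channel 8-bit [calibrated_image()].
#' @param threshold An [rgb_threshold()].
#' @return Logical mask of selected pixels.
#' @export
apply_rgb_threshold <- function(image, threshold) {
  stopifnot(is_calibrated_image(image), inherits(threshold, "rgb_threshold"))
  if (image$channels != 3L)
    stop("RGB thresholding needs a 3-channel image; convert grayscale ",
         "stainings upstream", call. = FALSE)
  px <- image$pixels
  (px[, , 1] >= threshold$r[1] & px[, , 1] <= threshold$r[2]) &
    (px[, , 2] >= threshold$g[1] & px[, , 2] <= threshold$g[2]) &
    (px[, , 3] >= threshold$b[1] & px[, , 3] <= threshold$b[2])
}

#' Quantify chromogenic staining area
#'
#' Counts the pixels of an RGB image falling inside the threshold
#' windows, optionally restricted to a polygon ROI and minus an
#' artefact-exclusion mask (e.g. bubbles), and converts the count to
#' um^2.
#'
#' @param image A 3-channel 8-bit [calibrated_image()].
#' @param threshold An [rgb_threshold()].
#' @param roi Optional [polygon_roi()] restricting the quantification.
#' @param exclude Optional logical mask of pixels to exclude.
#' @param image_id Identifier used in result tables.
#' @return A `stain_quant_result` with fields `selected_pixels`,
#'   `area_um2`, `roi_pixels` and the mask.
#' @export
quantify_stain_area <- function(image, threshold, roi = NULL,
                                exclude = NULL, image_id = "image") {
  mask <- apply_rgb_threshold(image, threshold)
  roi_px <- length(mask)
  if (!is.null(roi)) {
    roi_mask <- polygon_to_mask(roi, image)
    if (!any(roi_mask)) stop("ROI covers no pixels", call. = FALSE)
    roi_px <- sum(roi_mask)
    mask <- mask & roi_mask
  }
  if (!is.null(exclude)) {
    if (!identical(dim(exclude), img_dim(image)))
      stop("exclusion mask dimensions differ from the image",
           call. = FALSE)
    mask <- mask & !exclude
  }
  structure(list(image_id = image_id,
                 selected_pixels = sum(mask),
                 area_um2 = mask_area_um2(mask, image$pixel_size_um),
                 roi_pixels = roi_px,
                 threshold = threshold,
                 mask = mask),
            class = "stain_quant_result")
}

#' @export
print.stain_quant_result <- function(x, ...) {
  cat(sprintf("<stain_quant_result> %s: %d px = %.2f um^2\n",
              x$image_id, x$selected_pixels, x$area_um2))
  invisible(x)
}

#' @export
as.data.frame.stain_quant_result <- function(x, ...) {
  result_table(x$image_id, "stain_area", x$area_um2, "um2")
}

#' Quantify a folder of staining images with one constant threshold
#'
#' Applies the same threshold to every TIFF/PNG in a directory (the
#' constant-threshold rule that keeps areas comparable across a batch —
#' per-image threshold overrides are deliberately not accepted).
#'
#' @param dir Directory of images.
#' @param threshold An [rgb_threshold()] shared by the whole batch.
#' @param pixel_size_um Fallback calibration for images without
#'   metadata.
#' @param roi,exclude Passed to [quantify_stain_area()] for every image.
#' @return A result table (one `stain_area` row per image).
#' @export
quantify_stain_batch <- function(dir, threshold, pixel_size_um = NULL,
                                 roi = NULL, exclude = NULL) {
  files <- list.files(dir, pattern = "\\.(tif|tiff|png)$",
                      ignore.case = TRUE)
  if (!length(files)) stop("no images in ", dir, call. = FALSE)
  rows <- lapply(files, function(f) {
    img <- read_image(file.path(dir, f), pixel_size_um = pixel_size_um)
    as.data.frame(quantify_stain_area(img, threshold, roi = roi,
                                      exclude = exclude, image_id = f))
  })
  do.call(rbind, rows)
}

#' Write a threshold-preview overlay
#'
#' Writes the image with threshold-selected pixels highlighted in
#' magenta, supporting the visual trial-and-error calibration of the
#' threshold windows.
#'
#' @param image A 3-channel 8-bit [calibrated_image()].
#' @param threshold An [rgb_threshold()].
#' @param path Output PNG path.
#' @return The selection mask, invisibly.
#' @export
preview_threshold <- function(image, threshold, path) {
  mask <- apply_rgb_threshold(image, threshold)
  px <- image$pixels / 255
  r <- px[, , 1]; g <- px[, , 2]; b <- px[, , 3]
  r[mask] <- 1; g[mask] <- 0; b[mask] <- 1
  png::writePNG(array(c(r, g, b), dim = c(dim(mask), 3)), path)
  invisible(mask)
}
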