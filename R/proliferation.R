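#' Maximum-intensity projection
#'
#' Per-pixel maximum across a list of aligned single-channel slices;
#' mitotic-figure counting operates on such projections.
#'
#' @param stack List of single-channel [calibrated_image()]s with
#'   identical dimensions and calibration.
#' @return A [calibrated_image()] projection.
#' @export
max_project <- function(stack) {
  if (!is.list(stack) || !length(stack))
    stop("stack must be a non-empty list of images", call. = FALSE)
  stopifnot(all(vapply(stack, is_calibrated_image, logical(1))))
  ref <- stack[[1]]
  for (s in stack) {
    if (s$channels != 1L)
      stop("stack slices must be single-channel", call. = FALSE)
    if (!identical(img_dim(s), img_dim(ref)))
      stop("stack slices have differing dimensions", call. = FALSE)
    if (!isTRUE(all.equal(s$pixel_size_um, ref$pixel_size_um)))
      stop("stack slices have differing calibrations", call. = FALSE)
  }
  proj <- Reduce(pmax, lapply(stack, `[[`, "pixels"))
  calibrated_image(proj, ref$pixel_size_um, bit_depth = ref$bit_depth)
}

#' Spot filter parameters
#'
#' Mitotic figures are counted as bright connected components whose area
#' strictly exceeds `min_area_um2` and whose centroid lies within
#' `max_dist_um` (inclusive) of the caudal reference point.  Defaults
#' follow the assay: spots greater than 50 um^2 within 500 um of the
#' caudal end.
#'
#' @param caudal_point Caudal reference point `c(x, y)` in pixel
#'   coordinates.
#' @param min_area_um2 Strict lower area bound in um^2 (default 50).
#' @param max_dist_um Inclusive centroid-distance bound in um
#'   (default 500).
#' @param threshold `"auto"` for Otsu foreground detection, or an
#'   absolute intensity: pixels `>= threshold` are foreground.
#' @return A `spot_filter_params` object.
#' @export
spot_filter_params <- function(caudal_point, min_area_um2 = 50,
                               max_dist_um = 500, threshold = "auto") {
  stopifnot(length(caudal_point) == 2L, all(is.finite(caudal_point)),
            min_area_um2 >= 0, max_dist_um > 0)
  if (!identical(threshold, "auto") &&
      (!is.numeric(threshold) || length(threshold) != 1L))
    stop('threshold must be "auto" or a single intensity value',
         call. = FALSE)
  structure(list(caudal_point = as.numeric(caudal_point),
                 min_area_um2 = min_area_um2,
                 max_dist_um = max_dist_um,
                 threshold = threshold),
            class = "spot_filter_params")
}

#' Detect and count mitotic spots
#'
#' Thresholds the projection (Otsu or absolute), labels 8-connected
#' foreground components, and counts those passing the size and distance
#' filters of [spot_filter_params()].  A blank image yields count 0.
#'
#' @param image Single-channel [calibrated_image()] (typically a
#'   [max_project()] output).
#' @param params A [spot_filter_params()].
#' @return A `spot_count_result` with fields `count` and `spots` (a
#'   per-spot data.frame: label, area_um2, centroid, distance_um, the
#'   individual filter outcomes and `passed`).
#' @export
detect_spots <- function(image, params) {
  stopifnot(is_calibrated_image(image),
            inherits(params, "spot_filter_params"))
  if (image$channels != 1L)
    stop("spot detection needs a single-channel image", call. = FALSE)
  dm <- img_dim(image)
  cp <- params$caudal_point
  if (cp[1] < 0 || cp[1] > dm[2] || cp[2] < 0 || cp[2] > dm[1])
    stop("caudal point lies outside the image", call. = FALSE)
  m <- image$pixels
  maxval <- 2^image$bit_depth - 1
  if (identical(params$threshold, "auto")) {
    if (diff(range(m)) == 0) {
      fg <- matrix(FALSE, dm[1], dm[2])
    } else {
      thr <- EBImage::otsu(EBImage::Image(m / maxval), range = c(0, 1),
                           levels = 2^image$bit_depth) * maxval
      fg <- m > thr
    }
  } else {
    fg <- m >= params$threshold
  }
  ps <- image$pixel_size_um
  empty <- data.frame(label = integer(), area_um2 = numeric(),
                      centroid_x = numeric(), centroid_y = numeric(),
                      distance_um = numeric(), pass_area = logical(),
                      pass_distance = logical(), passed = logical())
  if (!any(fg))
    return(structure(list(count = 0L, spots = empty, params = params),
                     class = "spot_count_result"))
  lab <- label_components_cpp(fg, 8L)
  n <- max(lab)
  idx <- which(lab > 0)
  li <- lab[idx]
  area_px <- tabulate(li, n)
  cx <- (col(lab)[idx] - 0.5)
  cy <- (row(lab)[idx] - 0.5)
  cen_x <- rowsum(cx, li)[, 1] / area_px
  cen_y <- rowsum(cy, li)[, 1] / area_px
  dist_um <- sqrt((cen_x - cp[1])^2 + (cen_y - cp[2])^2) * ps
  spots <- data.frame(label = seq_len(n),
                      area_um2 = area_px * ps^2,
                      centroid_x = cen_x, centroid_y = cen_y,
                      distance_um = dist_um)
  spots$pass_area <- spots$area_um2 > params$min_area_um2   # strict
  spots$pass_distance <- spots$distance_um <= params$max_dist_um
  spots$passed <- spots$pass_area & spots$pass_distance
  structure(list(count = sum(spots$passed), spots = spots,
                 params = params),
            class = "spot_count_result")
}

#' @export
print.spot_count_result <- function(x, ...) {
  cat(sprintf("<spot_count_result> %d passing spot(s) of %d detected\n",
              x$count, nrow(x$spots)))
  invisible(x)
}

#' @export
as.data.frame.spot_count_result <- function(x, ..., image_id = "image") {
  result_table(image_id, "mitotic_spot_count", x$count, "count")
}
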