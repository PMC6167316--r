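#' Parameters for wound-ROS quantification
#'
#' The wound score is the mean fluorescence within `band_width_um` of the
#' wound edge minus the median fluorescence of a trunk reference band
#' whose near edge lies `trunk_offset_um` from the wound, measured
#' geodesically within the embryo (so distance follows the tissue, not
#' straight lines across concavities).  Defaults follow the assay: a
#' 50 um wound band and a trunk reference 1 mm distal; the trunk band
#' depth (100 um) and the wound-edge arc window (25 um around the
#' posterior-most extent of the embryo) are interpretation parameters and
#' configurable.
#'
#' @param band_width_um Depth of the wound band in um (default 50).
#' @param trunk_offset_um Geodesic distance from the wound edge to the
#'   near edge of the trunk reference band in um (default 1000).
#' @param trunk_band_um Depth of the trunk reference band in um
#'   (default 100).
#' @param edge_window_um Boundary pixels within this distance of the
#'   posterior-most (maximal-x) extent of the embryo form the wound-edge
#'   arc (default 25).
#' @return A `ros_quant_params` object.
#' @export
ros_quant_params <- function(band_width_um = 50, trunk_offset_um = 1000,
                             trunk_band_um = 100, edge_window_um = 25) {
  stopifnot(band_width_um > 0, trunk_offset_um > 0, trunk_band_um > 0,
            edge_window_um > 0)
  if (trunk_offset_um <= band_width_um)
    stop("trunk_offset_um must exceed band_width_um so the wound band ",
         "and trunk reference are disjoint", call. = FALSE)
  structure(list(band_width_um = band_width_um,
                 trunk_offset_um = trunk_offset_um,
                 trunk_band_um = trunk_band_um,
                 edge_window_um = edge_window_um),
            class = "ros_quant_params")
}

# Pixels of `m` with a 4-neighbour outside the mask or on the image edge.
mask_boundary <- function(m) {
  h <- nrow(m); w <- ncol(m)
  up    <- rbind(rep(FALSE, w), m[-h, , drop = FALSE])
  down  <- rbind(m[-1, , drop = FALSE], rep(FALSE, w))
  left  <- cbind(rep(FALSE, h), m[, -w, drop = FALSE])
  right <- cbind(m[, -1, drop = FALSE], rep(FALSE, h))
  m & !(up & down & left & right)
}

#' Detect the embryo outline from a brightfield image
#'
#' Automatic global (Otsu) thresholding with polarity chosen so the
#' embryo is the class under-represented on the image border (the border
#' is background; the embryo is darker in brightfield), followed by
#' largest 8-connected component selection and hole filling.  A provided
#' mask can be used instead wherever a `ros_quant` operation accepts
#' one.
#'
#' @param brightfield A single-channel [calibrated_image()].
#' @param min_fraction Minimum fraction of the image the embryo must
#'   cover; below this a detection-failure error is raised (default 1%).
#' @return Logical embryo mask.
#' @export
detect_embryo_outline <- function(brightfield, min_fraction = 0.01) {
  stopifnot(is_calibrated_image(brightfield))
  if (brightfield$channels != 1L)
    stop("brightfield must be single-channel", call. = FALSE)
  m <- brightfield$pixels
  maxval <- 2^brightfield$bit_depth - 1
  if (diff(range(m)) == 0)
    stop("embryo outline detection failed: image has no contrast",
         call. = FALSE)
  thr <- EBImage::otsu(EBImage::Image(m / maxval), range = c(0, 1),
                       levels = 2^brightfield$bit_depth) * maxval
  dark <- m <= thr
  # polarity: the image border is background, so the embryo is the class
  # under-represented there (darker than background in brightfield)
  border <- c(dark[1, ], dark[nrow(dark), ], dark[, 1], dark[, ncol(dark)])
  fg <- if (mean(border) < 0.5) dark else !dark
  lab <- label_components_cpp(fg, 8L)
  if (max(lab) == 0)
    stop("embryo outline detection failed: no foreground", call. = FALSE)
  sizes <- tabulate(lab[lab > 0])
  mask <- lab == which.max(sizes)
  mask <- EBImage::imageData(EBImage::fillHull(EBImage::Image(mask))) > 0.5
  if (sum(mask) < min_fraction * length(mask))
    stop("embryo outline detection failed: largest component below ",
         format(100 * min_fraction), "% of the image", call. = FALSE)
  mask
}

#' Geodesic distance from the wound edge
#'
#' The wound edge is the embryo boundary arc lying within
#' `edge_window_um` of the posterior-most (maximal-x) extent of the mask
#' (anterior is left by the imaging convention, so the amputation stump
#' is the rightmost part of the embryo).  Distances are geodesic within
#' the embryo mask, in um; pixels outside the mask are `NA`.
#'
#' @param embryo Logical embryo mask.
#' @param calibration A [pixel_calibration()] (or pixel size in um/px).
#' @param params A [ros_quant_params()].
#' @return List with `distance` (numeric matrix, um) and `edge_arc`
#'   (logical matrix).
#' @export
wound_distance_map <- function(embryo, calibration,
                               params = ros_quant_params()) {
  stopifnot(is.logical(embryo), is.matrix(embryo))
  if (!any(embryo)) stop("empty embryo mask", call. = FALSE)
  ps <- px_size(calibration)
  bnd <- mask_boundary(embryo)
  xc_um <- (col(embryo) - 0.5) * ps
  max_x <- max(xc_um[embryo])
  arc <- bnd & (xc_um >= max_x - params$edge_window_um)
  dist <- chamfer_geodesic(embryo, arc) * ps
  list(distance = dist, edge_arc = arc)
}

#' Wound band mask
#'
#' Embryo pixels within `band_width_um` (geodesically) of the wound-edge
#' arc; the region whose mean fluorescence forms the wound term of the
#' ROS score.
#'
#' @inheritParams wound_distance_map
#' @param distance Optional precomputed distance map from
#'   [wound_distance_map()], to avoid recomputation.
#' @return Logical mask, a subset of `embryo`.
#' @export
wound_band_mask <- function(embryo, calibration,
                            params = ros_quant_params(), distance = NULL) {
  if (is.null(distance))
    distance <- wound_distance_map(embryo, calibration, params)$distance
  band <- embryo & !is.na(distance) & distance <= params$band_width_um
  if (!any(band)) stop("empty wound band", call. = FALSE)
  band
}

#' Trunk reference mask
#'
#' Embryo pixels whose geodesic distance from the wound edge lies in
#' `[trunk_offset_um, trunk_offset_um + trunk_band_um]`; the region whose
#' median fluorescence estimates the basal oxidative state.
#'
#' @inheritParams wound_band_mask
#' @return Logical mask, disjoint from the wound band under valid
#'   parameters.
#' @export
trunk_reference_mask <- function(embryo, calibration,
                                 params = ros_quant_params(),
                                 distance = NULL) {
  if (is.null(distance))
    distance <- wound_distance_map(embryo, calibration, params)$distance
  lo <- params$trunk_offset_um
  hi <- params$trunk_offset_um + params$trunk_band_um
  ref <- embryo & !is.na(distance) & distance >= lo & distance <= hi
  if (!any(ref))
    stop("embryo does not extend ", lo, " um from the wound edge; ",
         "use a smaller trunk_offset_um", call. = FALSE)
  ref
}

#' Quantify wound-induced ROS fluorescence
#'
#' Computes `score = mean(fluorescence over the wound band) -
#' median(fluorescence over the trunk reference)`.  The subtraction
#' controls for the basal oxidative state of each embryo, so the score is
#' invariant under a uniform intensity offset.
#'
#' @param fluorescence Single-channel [calibrated_image()] of the ROS
#'   reporter.
#' @param brightfield Optional brightfield [calibrated_image()] from
#'   which the embryo outline is detected automatically.
#' @param embryo Optional logical embryo mask overriding detection (one
#'   of `brightfield` / `embryo` is required).
#' @param params A [ros_quant_params()].
#' @param image_id Identifier used in result tables.
#' @return A `ros_quant_result` with fields `wound_mean`, `trunk_median`,
#'   `score`, pixel counts, and the masks used.
#' @examples
#' \dontrun{
#' fx <- gen_wound_embryo(wound_scene_params(seed = 1))
#' quantify_wound_ros(fx$fluorescence, brightfield = fx$brightfield)
#' }
#' @export
quantify_wound_ros <- function(fluorescence, brightfield = NULL,
                               embryo = NULL,
                               params = ros_quant_params(),
                               image_id = "image") {
  stopifnot(is_calibrated_image(fluorescence))
  if (fluorescence$channels != 1L)
    stop("fluorescence must be single-channel", call. = FALSE)
  if (is.null(embryo)) {
    if (is.null(brightfield))
      stop("supply either a brightfield image or an embryo mask",
           call. = FALSE)
    if (!isTRUE(all.equal(brightfield$pixel_size_um,
                          fluorescence$pixel_size_um)))
      stop("brightfield and fluorescence calibrations differ",
           call. = FALSE)
    embryo <- detect_embryo_outline(brightfield)
  }
  if (!identical(dim(embryo), img_dim(fluorescence)))
    stop("embryo mask and fluorescence image dimensions differ",
         call. = FALSE)
  cal <- fluorescence$pixel_size_um
  dm <- wound_distance_map(embryo, cal, params)
  band <- wound_band_mask(embryo, cal, params, distance = dm$distance)
  trunk <- trunk_reference_mask(embryo, cal, params,
                                distance = dm$distance)
  fx <- fluorescence$pixels
  wound_mean <- mean(fx[band])
  trunk_median <- stats::median(fx[trunk])
  structure(list(image_id = image_id,
                 wound_mean = wound_mean,
                 trunk_median = trunk_median,
                 score = wound_mean - trunk_median,
                 band_pixels = sum(band),
                 trunk_pixels = sum(trunk),
                 params = params,
                 wound_band = band,
                 trunk_reference = trunk),
            class = "ros_quant_result")
}

#' @export
print.ros_quant_result <- function(x, ...) {
  cat(sprintf(paste0("<ros_quant_result> %s\n",
                     "  wound mean   : %.3f (%d px)\n",
                     "  trunk median : %.3f (%d px)\n",
                     "  score        : %.3f\n"),
              x$image_id, x$wound_mean, x$band_pixels,
              x$trunk_median, x$trunk_pixels, x$score))
  invisible(x)
}

#' @export
as.data.frame.ros_quant_result <- function(x, ...) {
  result_table(rep(x$image_id, 3),
               c("ros_wound_mean", "ros_trunk_median", "ros_score"),
               c(x$wound_mean, x$trunk_median, x$score),
               rep("intensity", 3))
}
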