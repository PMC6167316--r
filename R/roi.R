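#' Polygon region of interest
#'
#' A closed polygon given as ordered vertices in 0-based pixel
#' coordinates (x right/posterior, y down/ventral).  Used for manually
#' drawn regions: the notochord-bead outline, stain-quantification ROIs
#' and artefact-exclusion regions.
#'
#' @param x,y Numeric vertex coordinates (>= 3 vertices; the closing edge
#'   back to the first vertex is implicit).
#' @param name Optional ROI name.
#' @return A `polygon_roi` object.
#' @examples
#' sq <- polygon_roi(c(0, 10, 10, 0), c(0, 0, 10, 10))
#' polygon_area(sq, pixel_calibration(1))
#' @export
polygon_roi <- function(x, y, name = "roi") {
  if (length(x) != length(y) || length(x) < 3L)
    stop("a polygon needs at least 3 vertices", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("polygon vertices must be finite", call. = FALSE)
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 name = as.character(name)),
            class = "polygon_roi")
}

#' @export
print.polygon_roi <- function(x, ...) {
  cat(sprintf("<polygon_roi> '%s', %d vertices\n", x$name, length(x$x)))
  invisible(x)
}

#' Read a polygon ROI from a landmark CSV
#'
#' Rows sharing the same `name` are taken as the ordered vertices of one
#' polygon.
#'
#' @param path CSV with header `name,x,y`.
#' @param name ROI name to extract; defaults to the first name in the
#'   file.
#' @return A [polygon_roi()].
#' @export
read_polygon_roi <- function(path, name = NULL) {
  df <- read_landmarks(path)
  name <- name %||% df$name[1]
  df <- df[df$name == name, ]
  if (nrow(df) < 3L)
    stop("ROI '", name, "' has fewer than 3 vertices", call. = FALSE)
  polygon_roi(df$x, df$y, name = name)
}

#' Polygon area in square micrometres
#'
#' Shoelace area of the (simple) polygon scaled by the squared pixel
#' size.  Orientation-independent; the same primitive the bead-area
#' measurement uses.  A degenerate polygon returns 0 with a warning.
#'
#' @param roi A [polygon_roi()].
#' @param calibration A [pixel_calibration()] (or pixel size in um/px).
#' @return Area in um^2.
#' @export
polygon_area <- function(roi, calibration) {
  stopifnot(inherits(roi, "polygon_roi"))
  ps <- px_size(calibration)
  x <- roi$x; y <- roi$y
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  a_px <- abs(sum(x[j] * y - x * y[j])) / 2
  if (a_px == 0) warning("degenerate polygon: area is zero")
  a_px * ps^2
}

# Even-odd (crossing number) point-in-polygon test, vectorised over
# points.  Points exactly on an edge follow the rule's tie outcome.
points_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py))
    if (any(crosses)) {
      xint <- (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i]
      inside <- xor(inside, crosses & (px < xint))
    }
    j <- i
  }
  inside
}

#' Rasterise a polygon ROI to a pixel mask
#'
#' A pixel is included iff its centre `(c - 0.5, r - 0.5)` lies inside
#' the polygon under the even-odd rule.  Vertices outside the image are
#' clipped with a warning; a polygon entirely outside yields an empty
#' mask.
#'
#' @param roi A [polygon_roi()].
#' @param image A [calibrated_image()] (or a `c(height, width)` integer
#'   vector) defining the raster.
#' @return A logical matrix of the image dimensions.
#' @export
polygon_to_mask <- function(roi, image) {
  stopifnot(inherits(roi, "polygon_roi"))
  dm <- if (is_calibrated_image(image)) img_dim(image) else as.integer(image)
  h <- dm[1]; w <- dm[2]
  if (any(roi$x < 0) || any(roi$x > w) || any(roi$y < 0) || any(roi$y > h))
    warning("polygon extends beyond the image and was clipped")
  mask <- matrix(FALSE, h, w)
  c0 <- max(1L, floor(min(roi$x) + 0.5))
  c1 <- min(w, ceiling(max(roi$x) + 0.5))
  r0 <- max(1L, floor(min(roi$y) + 0.5))
  r1 <- min(h, ceiling(max(roi$y) + 0.5))
  if (c0 > c1 || r0 > r1) return(mask)
  cols <- c0:c1; rows <- r0:r1
  cx <- rep(cols - 0.5, each = length(rows))
  cy <- rep(rows - 0.5, times = length(cols))
  inside <- points_in_polygon(cx, cy, roi$x, roi$y)
  mask[rows, cols] <- matrix(inside, length(rows), length(cols))
  mask
}

#' Area of a pixel mask in square micrometres
#'
#' @param mask Logical matrix.
#' @param calibration A [pixel_calibration()] (or pixel size in um/px).
#' @return `sum(mask) * pixel_size_um^2`.
#' @export
mask_area_um2 <- function(mask, calibration) {
  sum(mask) * px_size(calibration)^2
}
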