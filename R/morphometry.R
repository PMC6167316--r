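#' Membrane triple
#'
#' Three points characterising the bowing of a notochord cell membrane:
#' the two points where the membrane contacts the notochord sheath and
#' the membrane point furthest from the chord between them (the apex).
#' The circle through the three points approximates the membrane arc;
#' its inverse radius is the Menger curvature.
#'
#' @param sheath_a,sheath_b Sheath-contact points, each `c(x, y)` in
#'   pixel coordinates.
#' @param apex Apex point `c(x, y)`.
#' @param calibration A [pixel_calibration()] (or pixel size in um/px).
#' @return A `membrane_triple` object.
#' @export
membrane_triple <- function(sheath_a, sheath_b, apex, calibration = 1) {
  pts <- rbind(sheath_a, sheath_b, apex)
  if (ncol(pts) != 2L || !all(is.finite(pts)))
    stop("points must be finite c(x, y) pairs", call. = FALSE)
  structure(list(sheath_a = as.numeric(sheath_a),
                 sheath_b = as.numeric(sheath_b),
                 apex = as.numeric(apex),
                 pixel_size_um = px_size(calibration)),
            class = "membrane_triple")
}

#' Signed Menger curvature of a membrane triple
#'
#' The unsigned curvature is `4A / (a b c)` where `A` is the area of the
#' triangle through the three points and `a, b, c` its side lengths (in
#' um), i.e. the inverse circumradius.  The sign encodes the bow
#' direction with respect to the body axis (anterior left): positive when
#' the apex lies posterior (greater x) to the chord through the sheath
#' contacts — equivalently, circumcentre anterior — and negative for an
#' anterior bow.  A membrane running perpendicular to the sheath (the
#' three points collinear) has curvature exactly 0; collinearity is
#' declared when the sine of the apex angle falls below `tol`.
#'
#' Apex-vs-chord laterality is used for the sign rather than the
#' circumcentre position: the two agree for any circle, but the
#' circumcentre diverges as the membrane straightens while the apex
#' offset stays finite.  For a chord lying exactly parallel to the body
#' axis (no anterior/posterior laterality) the magnitude is reported
#' with positive sign.
#'
#' @param triple A [membrane_triple()].
#' @param tol Collinearity tolerance on the sine of the apex angle
#'   (default 1e-9).
#' @return A `curvature_result` with fields `kappa` (um^-1, signed),
#'   `radius_um` (`Inf` when straight) and `sign` (+1, 0, -1).
#' @examples
#' tr <- membrane_triple(c(0, 0), c(0, 100), c(10, 50), calibration = 1)
#' menger_curvature(tr)$kappa   # posterior bow: positive
#' @export
menger_curvature <- function(triple, tol = 1e-9) {
  stopifnot(inherits(triple, "membrane_triple"))
  ps <- triple$pixel_size_um
  A <- triple$sheath_a * ps
  B <- triple$sheath_b * ps
  P <- triple$apex * ps
  ab <- sqrt(sum((B - A)^2))
  ap <- sqrt(sum((P - A)^2))
  bp <- sqrt(sum((P - B)^2))
  if (min(ab, ap, bp) == 0)
    stop("membrane triple has coincident points", call. = FALSE)
  cross <- (B[1] - A[1]) * (P[2] - A[2]) - (B[2] - A[2]) * (P[1] - A[1])
  area2 <- abs(cross)                       # = 2 * triangle area
  sin_apex <- area2 / (ap * bp)
  if (sin_apex < tol) {
    res <- list(kappa = 0, radius_um = Inf, sign = 0L)
  } else {
    kabs <- 2 * area2 / (ab * ap * bp)      # 4A / (abc)
    # apex laterality: component of (apex - chord) along +x
    u <- (B - A) / ab
    foot <- A + sum((P - A) * u) * u
    sgn <- sign((P - foot)[1])
    # a chord exactly parallel to the body axis has no anterior/posterior
    # laterality; report the magnitude with positive sign
    if (sgn == 0) sgn <- 1
    res <- list(kappa = sgn * kabs,
                radius_um = 1 / kabs,
                sign = as.integer(sgn))
  }
  structure(c(res, list(triple = triple)), class = "curvature_result")
}

#' @export
print.curvature_result <- function(x, ...) {
  cat(sprintf("<curvature_result> kappa = %.6g um^-1 (R = %.6g um, %s)\n",
              x$kappa, x$radius_um,
              c("anterior bow", "straight", "posterior bow")[x$sign + 2]))
  invisible(x)
}

#' Axial length of a segment
#'
#' Length of the projection of `end - start` onto a body-axis direction,
#' in um — the rectangle-parallel-to-the-body measurement used for tail
#' length (anus to caudal end of the fin fold) and regrowth (end of the
#' notochord to caudal end of the fin fold).  Perpendicular displacement
#' of either endpoint does not change the result.
#'
#' @param start,end Points `c(x, y)` in pixel coordinates.
#' @param axis Direction vector `c(dx, dy)` of the body axis (any
#'   non-zero length; normalised internally).  Default: the
#'   anterior-posterior image axis.
#' @param calibration A [pixel_calibration()] (or pixel size in um/px).
#' @return Length in um (non-negative).
#' @export
measure_axial_length <- function(start, end, axis = c(1, 0),
                                 calibration = 1) {
  axis <- as.numeric(axis)
  nrm <- sqrt(sum(axis^2))
  if (!is.finite(nrm) || nrm == 0)
    stop("axis must be a non-zero vector", call. = FALSE)
  u <- axis / nrm
  abs(sum((as.numeric(end) - as.numeric(start)) * u)) * px_size(calibration)
}

#' Trunk contraction between paired landmark sets
#'
#' The trunk span is measured between two named landmarks (somite
#' boundaries roughly eight somites apart) in the pre-excision and
#' post-excision images, projected on the body axis, and the contraction
#' is `100 * (L_pre - L_post) / L_pre` percent.
#'
#' @param pre,post Landmark data.frames with columns `name,x,y` (see
#'   [read_landmarks()]), both containing the two named landmarks.
#' @param landmarks Character vector of the two landmark names bounding
#'   the span; defaults to the first and last landmark of `pre`.
#' @param axis Body-axis direction passed to [measure_axial_length()].
#' @param calibration A [pixel_calibration()] (or pixel size in um/px).
#' @return A `contraction_result` with fields `L_pre_um`, `L_post_um`,
#'   `contraction_percent`.
#' @export
measure_contraction <- function(pre, post, landmarks = NULL,
                                axis = c(1, 0), calibration = 1) {
  stopifnot(all(c("name", "x", "y") %in% names(pre)),
            all(c("name", "x", "y") %in% names(post)))
  landmarks <- landmarks %||% pre$name[c(1L, nrow(pre))]
  if (length(landmarks) != 2L)
    stop("exactly two landmark names are required", call. = FALSE)
  span <- function(df, which) {
    miss <- setdiff(landmarks, df$name)
    if (length(miss))
      stop("landmark(s) missing from ", which, " set: ",
           paste(miss, collapse = ", "), call. = FALSE)
    p1 <- unlist(df[match(landmarks[1], df$name), c("x", "y")])
    p2 <- unlist(df[match(landmarks[2], df$name), c("x", "y")])
    measure_axial_length(p1, p2, axis, calibration)
  }
  L_pre <- span(pre, "pre")
  L_post <- span(post, "post")
  if (L_pre <= 0) stop("pre-excision span is zero", call. = FALSE)
  structure(list(L_pre_um = L_pre, L_post_um = L_post,
                 contraction_percent = 100 * (L_pre - L_post) / L_pre,
                 landmarks = landmarks),
            class = "contraction_result")
}

#' @export
print.contraction_result <- function(x, ...) {
  cat(sprintf(
    "<contraction_result> %.2f um -> %.2f um: %.3f%% contraction\n",
    x$L_pre_um, x$L_post_um, x$contraction_percent))
  invisible(x)
}

#' Notochord bead area
#'
#' Area of a manually traced bead outline, in um^2 (shoelace area of the
#' polygon ROI).
#'
#' @param roi A [polygon_roi()] tracing the bead.
#' @param calibration A [pixel_calibration()] (or pixel size in um/px).
#' @return Area in um^2.
#' @export
bead_area <- function(roi, calibration) polygon_area(roi, calibration)

#' Select the notochord cell to score for membrane curvature
#'
#' Among membrane traces that span the width of the notochord (touch
#' both sheath lines) and are not bent by contact with other cell
#' membranes, selects the cell nearest the line 600 um anterior to the
#' stump, looking only at cells within that distance of the stump.  The
#' chosen trace's triple is built from its two chain endpoints (the
#' sheath contacts) and the chain point furthest from the chord between
#' them (ties broken by smallest y).
#'
#' @param traces Data.frame of membrane point-chains with columns
#'   `trace_id, x, y`, points ordered along each chain from one sheath
#'   contact to the other.
#' @param annotations Data.frame with columns `trace_id`, `spans_band`
#'   (logical: touches both sheath lines) and `bent` (logical: contacts
#'   another membrane, ineligible).
#' @param stump_x Posterior stump x position in pixel coordinates.
#' @param max_dist_um Selection window anterior of the stump (default
#'   600).
#' @param calibration A [pixel_calibration()] (or pixel size in um/px).
#' @return List with `trace_id` and the built [membrane_triple()].
#' @export
select_measurement_cell <- function(traces, annotations, stump_x,
                                    max_dist_um = 600, calibration = 1) {
  stopifnot(all(c("trace_id", "x", "y") %in% names(traces)),
            all(c("trace_id", "spans_band", "bent") %in% names(annotations)))
  ps <- px_size(calibration)
  pos <- vapply(split(traces$x, traces$trace_id), mean, numeric(1))
  ann <- annotations[match(names(pos), annotations$trace_id), ]
  dist_um <- (stump_x - pos) * ps
  eligible <- ann$spans_band & !ann$bent &
    dist_um >= 0 & dist_um <= max_dist_um
  if (!any(eligible, na.rm = TRUE))
    stop("no eligible membrane trace (spanning, unbent, within ",
         max_dist_um, " um of the stump)", call. = FALSE)
  cand <- names(pos)[which(eligible)]
  chosen <- cand[which.max(dist_um[cand])]   # nearest the 600 um line
  chain <- traces[traces$trace_id == chosen, ]
  a <- unlist(chain[1L, c("x", "y")])
  b <- unlist(chain[nrow(chain), c("x", "y")])
  u <- (b - a) / sqrt(sum((b - a)^2))
  rel <- cbind(chain$x - a[1], chain$y - a[2])
  perp <- abs(rel[, 1] * u[2] - rel[, 2] * u[1])
  best <- which(perp == max(perp))
  if (length(best) > 1L) best <- best[which.min(chain$y[best])]
  list(trace_id = chosen,
       triple = membrane_triple(a, b,
                                unlist(chain[best, c("x", "y")]),
                                calibration = ps))
}
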