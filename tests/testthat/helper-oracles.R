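# Independent geometric oracles used across tests.

# Exact circumcircle through three points by solving the perpendicular-
# bisector linear system; returns the radius (independent of the
# 4A/(abc) route the package uses).
oracle_circumradius <- function(a, b, p) {
  M <- 2 * rbind(b - a, p - a)
  rhs <- c(sum(b^2) - sum(a^2), sum(p^2) - sum(a^2))
  centre <- solve(M, rhs)
  sqrt(sum((centre - a)^2))
}

# Brute-force Euclidean distance (um) from each pixel centre of `mask`
# to the nearest TRUE pixel centre of `sources`; small fixtures only.
oracle_euclidean_to_set <- function(mask, sources, pixel_size_um) {
  src <- which(sources, arr.ind = TRUE)
  px <- which(mask, arr.ind = TRUE)
  d <- outer(px[, 1], src[, 1], `-`)^2 + outer(px[, 2], src[, 2], `-`)^2
  out <- matrix(NA_real_, nrow(mask), ncol(mask))
  out[px] <- sqrt(apply(d, 1, min)) * pixel_size_um
  out
}

# A rectangle "embryo" mask with its wound at the right edge.
rect_embryo <- function(h_px, w_px, img_h, img_w, r0 = 10, c0 = 10) {
  m <- matrix(FALSE, img_h, img_w)
  m[r0:(r0 + h_px - 1), c0:(c0 + w_px - 1)] <- TRUE
  m
}

# Small wound scene used repeatedly: ~1.4 mm embryo so trunk offsets fit.
small_wound_params <- function(...) {
  wound_scene_params(width_um = 1600, height_um = 240,
                     body_semi_x_um = 760, body_semi_y_um = 95,
                     body_centre_um = c(770, 120), wound_x_um = 1380, ...)
}
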