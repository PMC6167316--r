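#' Synthetic fixture generators
#'
#' Every stage of the pipeline has a seeded generator that renders a
#' ground-truthed input plus a machine-readable manifest, so parameter
#' recovery can be tested without raw micrographs.  Disks and silhouettes
#' are rasterised by pixel-centre inclusion and the manifest records the
#' rasterised pixel count (not the analytic area), so noiseless
#' assertions are exact.  The same seed and parameters reproduce outputs
#' bit-identically.
#'
#' @name synthetic-fixtures
NULL

# Exact-count disk rasterisation: the `target_px` pixels nearest `centre`
# (pixel coordinates), ties broken by row then column, as linear indices
# into an h x w matrix.  Errors if the disk does not fit in the image.
disk_pixels <- function(centre, target_px, h, w) {
  if (target_px < 1) stop("disk needs at least one pixel", call. = FALSE)
  r0 <- sqrt(target_px / pi) + 2
  c_lo <- max(1L, floor(centre[1] - r0)); c_hi <- min(w, ceiling(centre[1] + r0))
  r_lo <- max(1L, floor(centre[2] - r0)); r_hi <- min(h, ceiling(centre[2] + r0))
  cols <- c_lo:c_hi; rows <- r_lo:r_hi
  cc <- rep(cols, each = length(rows))
  rr <- rep(rows, times = length(cols))
  d2 <- (cc - 0.5 - centre[1])^2 + (rr - 0.5 - centre[2])^2
  ord <- order(d2, rr, cc)
  if (length(ord) < target_px ||
      sqrt(d2[ord[target_px]]) > r0 - 1)
    stop("disk extends outside the image", call. = FALSE)
  sel <- ord[seq_len(target_px)]
  rr[sel] + (cc[sel] - 1L) * h
}

# clip + round additive Gaussian noise onto an integer-scale raster
add_noise <- function(px, sigma, maxval) {
  if (sigma <= 0) return(px)
  out <- px + stats::rnorm(length(px), 0, sigma)
  out <- pmin(pmax(round(out), 0), maxval)
  if (is.matrix(px)) matrix(out, nrow(px), ncol(px)) else
    array(out, dim(px))
}

#' Parameters of the synthetic wound-embryo scene
#'
#' The embryo silhouette is an ellipse truncated at a vertical amputation
#' plane (the posterior wound); fluorescence is `basal_intensity` inside
#' the embryo and `band_intensity` within `band_width_um` (geodesically)
#' of the wound edge, plus optional Gaussian noise.  The ground-truth ROS
#' score is `band_intensity - basal_intensity`.
#'
#' @param band_intensity,basal_intensity Fluorescence inside/outside the
#'   wound band (8-bit scale; `band_intensity >= basal_intensity >= 0`).
#' @param band_width_um Width of the elevated band in um (> 0).
#' @param noise_sigma Gaussian noise SD added to both channels.
#' @param width_um,height_um Image extent in um.
#' @param body_semi_x_um,body_semi_y_um Ellipse semi-axes in um.
#' @param body_centre_um Ellipse centre `c(x, y)` in um.
#' @param wound_x_um Amputation plane (posterior truncation) in um.
#' @param embryo_gray,background_gray Brightfield intensities (embryo
#'   darker).
#' @param pixel_size_um Calibration (default 1 um/px so pixel and
#'   physical units coincide).
#' @param seed Optional integer seed.
#' @return A `wound_scene_params` object.
#' @export
wound_scene_params <- function(band_intensity = 200, basal_intensity = 50,
                               band_width_um = 50, noise_sigma = 0,
                               width_um = 2200, height_um = 360,
                               body_semi_x_um = 1050, body_semi_y_um = 140,
                               body_centre_um = c(1060, 180),
                               wound_x_um = 1900,
                               embryo_gray = 40, background_gray = 220,
                               pixel_size_um = 1, seed = NULL) {
  if (!(band_intensity >= basal_intensity && basal_intensity >= 0))
    stop("need band_intensity >= basal_intensity >= 0", call. = FALSE)
  stopifnot(band_width_um > 0, noise_sigma >= 0,
            band_intensity <= 255, embryo_gray < background_gray)
  structure(as.list(environment()), class = "wound_scene_params")
}

#' Generate a synthetic wound embryo (brightfield + fluorescence)
#'
#' @param params A [wound_scene_params()].
#' @return List with `brightfield` and `fluorescence`
#'   ([calibrated_image()]s), the true `embryo_mask`, and `manifest`.
#' @seealso [quantify_wound_ros()]
#' @export
gen_wound_embryo <- function(params) {
  stopifnot(inherits(params, "wound_scene_params"))
  p <- params
  ps <- p$pixel_size_um
  w <- round(p$width_um / ps); h <- round(p$height_um / ps)
  xc <- (matrix(seq_len(w), h, w, byrow = TRUE) - 0.5) * ps
  yc <- (matrix(seq_len(h), h, w) - 0.5) * ps
  mask <- ((xc - p$body_centre_um[1]) / p$body_semi_x_um)^2 +
    ((yc - p$body_centre_um[2]) / p$body_semi_y_um)^2 <= 1 &
    xc <= p$wound_x_um
  if (!any(mask)) stop("empty embryo silhouette", call. = FALSE)
  dm <- wound_distance_map(mask, ps)
  if (all(dm$distance[mask] <= p$band_width_um))
    stop("wound band is wider than the embryo", call. = FALSE)
  band <- mask & !is.na(dm$distance) & dm$distance <= p$band_width_um

  bf <- matrix(p$background_gray, h, w)
  bf[mask] <- p$embryo_gray
  fl <- matrix(0, h, w)
  fl[mask] <- p$basal_intensity
  fl[band] <- p$band_intensity
  with_seed(p$seed, {
    bf <- add_noise(bf, p$noise_sigma, 255)
    fl <- add_noise(fl, p$noise_sigma, 255)
  })
  manifest <- list(
    generator = "wound_embryo", seed = p$seed, pixel_size_um = ps,
    band_intensity = p$band_intensity, basal_intensity = p$basal_intensity,
    band_width_um = p$band_width_um, noise_sigma = p$noise_sigma,
    wound_x_um = p$wound_x_um,
    truth = list(score = p$band_intensity - p$basal_intensity,
                 silhouette_area_um2 = sum(mask) * ps^2,
                 band_pixels = sum(band)))
  list(brightfield = calibrated_image(bf, ps),
       fluorescence = calibrated_image(fl, ps),
       embryo_mask = mask,
       manifest = manifest)
}

#' Generate a synthetic chromogenic staining image
#'
#' Renders coloured disks of exactly known pixel area on a uniform
#' tissue-coloured background.  Blobs flagged as artefacts stand in for
#' staining artefacts (e.g. bubbles) to be excluded during
#' quantification.
#'
#' @param blobs List of blobs, each a list with `colour` (RGB in 0--255),
#'   `area_um2`, `centre` (`c(x, y)` pixel coordinates) and optional
#'   `artefact = TRUE`.  Blobs must be disjoint and coloured differently
#'   from the background.
#' @param background Background RGB (default a pale tissue tone).
#' @param width_um,height_um Image extent in um.
#' @param pixel_size_um Calibration (default 1).
#' @param noise_sigma Per-channel Gaussian noise SD.
#' @param seed Optional integer seed.
#' @return List with `image` ([calibrated_image()]) and `manifest`
#'   (per-blob rasterised areas and artefact flags).
#' @export
gen_stain_image <- function(blobs, background = c(235, 230, 220),
                            width_um = 400, height_um = 300,
                            pixel_size_um = 1, noise_sigma = 0,
                            seed = NULL) {
  ps <- pixel_size_um
  w <- round(width_um / ps); h <- round(height_um / ps)
  px <- array(rep(background, each = h * w), dim = c(h, w, 3))
  occupied <- matrix(FALSE, h, w)
  entries <- vector("list", length(blobs))
  for (i in seq_along(blobs)) {
    b <- blobs[[i]]
    if (all(b$colour == background))
      stop("blob colour equals the background colour", call. = FALSE)
    npx <- round(b$area_um2 / ps^2)
    idx <- disk_pixels(b$centre, npx, h, w)
    if (any(occupied[idx])) stop("blobs overlap", call. = FALSE)
    occupied[idx] <- TRUE
    for (ch in 1:3) {
      plane <- px[, , ch]
      plane[idx] <- b$colour[ch]
      px[, , ch] <- plane
    }
    entries[[i]] <- list(colour = b$colour, centre = b$centre,
                         pixels = npx, area_um2 = npx * ps^2,
                         artefact = isTRUE(b$artefact))
  }
  px <- with_seed(seed, add_noise(px, noise_sigma, 255))
  manifest <- list(generator = "stain_image", seed = seed,
                   pixel_size_um = ps, background = background,
                   noise_sigma = noise_sigma, blobs = entries,
                   truth = list(
                     stain_area_um2 = sum(vapply(entries, function(e)
                       if (e$artefact) 0 else e$area_um2, numeric(1)))))
  list(image = calibrated_image(px, ps), manifest = manifest)
}

#' Generate membrane triples with known curvature
#'
#' Constructs sheath-contact and apex points lying exactly on circles of
#' stated radius, bowing posteriorly (`kappa = +1/R`), anteriorly
#' (`kappa = -1/R`) or collinear (`kappa = 0`), with the chord
#' perpendicular to the body axis as notochord cell membranes are.
#'
#' @param cases Data.frame with columns `radius_um` (ignored for
#'   straight cases) and `bow` (`"posterior"`, `"anterior"` or
#'   `"straight"`).
#' @param chord_span_um Distance between the sheath contacts (notochord
#'   width), default 40 um.
#' @param pixel_size_um Calibration (default 1).
#' @param seed Optional seed for the (irrelevant to curvature) placement
#'   of each triple.
#' @return List of cases, each with `triple` ([membrane_triple()]),
#'   `kappa_true` and `bow`.
#' @export
gen_membrane_triples <- function(cases, chord_span_um = 40,
                                 pixel_size_um = 1, seed = NULL) {
  stopifnot(all(c("radius_um", "bow") %in% names(cases)))
  if (!all(cases$bow %in% c("posterior", "anterior", "straight")))
    stop('bow must be "posterior", "anterior" or "straight"',
         call. = FALSE)
  ps <- pixel_size_um
  s <- chord_span_um
  with_seed(seed, {
    x0 <- stats::runif(nrow(cases), 200, 1800)
    y0 <- stats::runif(nrow(cases), 100, 260)
    lapply(seq_len(nrow(cases)), function(i) {
      bow <- cases$bow[i]
      R <- cases$radius_um[i]
      a <- c(x0[i], y0[i] - s / 2)
      b <- c(x0[i], y0[i] + s / 2)
      if (bow == "straight") {
        apex <- c(x0[i], y0[i])
        k <- 0
      } else {
        if (!is.finite(R) || R <= 0)
          stop("curved cases need radius_um > 0", call. = FALSE)
        if (R < s / 2)
          stop("radius smaller than half the chord span", call. = FALSE)
        d <- sqrt(R^2 - (s / 2)^2)
        dir <- if (bow == "posterior") 1 else -1
        # circumcentre sits opposite the bow; apex at centre + dir * R
        apex <- c(x0[i] - dir * d + dir * R, y0[i])
        k <- dir / R
      }
      list(triple = membrane_triple(a / ps, b / ps, apex / ps,
                                    calibration = ps),
           kappa_true = k, bow = bow,
           radius_um = if (bow == "straight") Inf else R)
    })
  })
}

#' Ground-truth contraction presets
#'
#' Mean trunk contraction (percent, 2 h post excision) of the study
#' conditions the generator emulates: untreated larvae contract by 4.4%
#' on average, DPI-treated by 1.7% and PP2-treated by 1.2%.
#'
#' @return Named numeric vector of contraction percentages.
#' @export
contraction_presets <- function() {
  c(untreated = 4.4, dpi = 1.7, pp2 = 1.2)
}

#' Parameters of a synthetic contraction landmark pair
#'
#' @param true_contraction_percent Ground-truth axial contraction
#'   (`0 <= c < 100`); see [contraction_presets()] for the study-group
#'   means.
#' @param n_landmarks Number of somite-boundary proxy landmarks along
#'   the span (default 8, roughly one per somite).
#' @param span_um Pre-excision distance between the first and last
#'   landmark (default 800 um, about eight somites).
#' @param jitter_sigma_um SD of Gaussian placement error added to each
#'   post-excision coordinate (default 0).
#' @param start_x_um,y_um Anterior landmark position in um.
#' @param axis Body-axis direction (default anterior-posterior).
#' @param pixel_size_um Calibration (default 1).
#' @param seed Optional integer seed.
#' @return A `contraction_params` object.
#' @export
contraction_params <- function(true_contraction_percent,
                               n_landmarks = 8, span_um = 800,
                               jitter_sigma_um = 0, start_x_um = 400,
                               y_um = 180, axis = c(1, 0),
                               pixel_size_um = 1, seed = NULL) {
  if (!(true_contraction_percent >= 0 && true_contraction_percent < 100))
    stop("true_contraction_percent must be in [0, 100)", call. = FALSE)
  stopifnot(n_landmarks >= 2, span_um > 0, jitter_sigma_um >= 0)
  structure(as.list(environment()), class = "contraction_params")
}

#' Generate a pre/post landmark pair with known contraction
#'
#' Pre-excision landmarks are somite-boundary proxies spaced along the
#' body axis (internal spacings perturbed for realism; the two endpoint
#' landmarks sit exactly `span_um` apart).  Post-excision landmarks are
#' the pre positions scaled by `1 - c/100` along the axis about the
#' anterior endpoint, plus Gaussian placement jitter on each coordinate.
#' With zero jitter, [measure_contraction()] recovers `c` exactly.
#'
#' @param params A [contraction_params()].
#' @param out_dir Optional directory; when given, writes `pre.csv`,
#'   `post.csv` and `manifest.json` there.
#' @return List with `pre`, `post` (landmark data.frames) and
#'   `manifest`.
#' @export
gen_contraction_pair <- function(params, out_dir = NULL) {
  stopifnot(inherits(params, "contraction_params"))
  p <- params
  n <- p$n_landmarks
  ps <- p$pixel_size_um
  u <- p$axis / sqrt(sum(p$axis^2))
  with_seed(p$seed, {
    frac <- seq(0, 1, length.out = n)
    if (n > 2)  # perturb interior somite boundaries, keep order
      frac[2:(n - 1)] <- sort(frac[2:(n - 1)] +
                                stats::runif(n - 2, -0.4, 0.4) / (n - 1))
    along <- p$span_um * frac
    pre_x <- (p$start_x_um + along * u[1]) / ps
    pre_y <- (p$y_um + along * u[2]) / ps
    scale <- 1 - p$true_contraction_percent / 100
    post_x <- (p$start_x_um + along * scale * u[1]) / ps
    post_y <- (p$y_um + along * scale * u[2]) / ps
    if (p$jitter_sigma_um > 0) {
      post_x <- post_x + stats::rnorm(n, 0, p$jitter_sigma_um) / ps
      post_y <- post_y + stats::rnorm(n, 0, p$jitter_sigma_um) / ps
    }
    nm <- sprintf("somite_%02d", seq_len(n))
    pre <- data.frame(name = nm, x = pre_x, y = pre_y,
                      stringsAsFactors = FALSE)
    post <- data.frame(name = nm, x = post_x, y = post_y,
                       stringsAsFactors = FALSE)
    manifest <- list(generator = "contraction_pair", seed = p$seed,
                     pixel_size_um = ps,
                     true_contraction_percent = p$true_contraction_percent,
                     jitter_sigma_um = p$jitter_sigma_um,
                     span_um = p$span_um, n_landmarks = n,
                     landmark_pair = nm[c(1L, n)])
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_landmarks(pre, file.path(out_dir, "pre.csv"))
      write_landmarks(post, file.path(out_dir, "post.csv"))
      write_manifest(manifest, file.path(out_dir, "manifest.json"))
    }
    list(pre = pre, post = post, manifest = manifest)
  })
}

#' Generate a synthetic mitotic-spot image
#'
#' Renders bright disks of exactly known pixel area at stated centroid
#' distances from a caudal reference point, on a dark background.  The
#' manifest records, for each spot, the rasterised area and the
#' rasterised-centroid distance, and whether it passes the default
#' size/distance filter, plus the expected passing count.
#'
#' @param spots Data.frame with columns `area_um2`, `distance_um` and
#'   optionally `angle_deg` (direction from the caudal point; drawn
#'   uniformly in \[-55, 55\] degrees when absent).
#' @param caudal_point Caudal reference `c(x, y)` in pixel coordinates.
#' @param width_um,height_um Image extent in um.
#' @param intensity Spot intensity (8-bit scale; background 0).
#' @param min_area_um2,max_dist_um Filter the manifest's expected count
#'   is computed with (defaults 50 / 500).
#' @param pixel_size_um Calibration (default 1).
#' @param noise_sigma Gaussian noise SD.
#' @param seed Optional integer seed.
#' @return List with `image` ([calibrated_image()]) and `manifest`.
#' @seealso [detect_spots()]
#' @export
gen_spot_image <- function(spots, caudal_point = c(80, 300),
                           width_um = 800, height_um = 600,
                           intensity = 220, min_area_um2 = 50,
                           max_dist_um = 500, pixel_size_um = 1,
                           noise_sigma = 0, seed = NULL) {
  stopifnot(all(c("area_um2", "distance_um") %in% names(spots)))
  ps <- pixel_size_um
  w <- round(width_um / ps); h <- round(height_um / ps)
  with_seed(seed, {
    angle <- if ("angle_deg" %in% names(spots)) spots$angle_deg else
      rep(NA_real_, nrow(spots))
    angle[is.na(angle)] <- stats::runif(sum(is.na(angle)), -55, 55)
    theta <- angle * pi / 180
    cx <- caudal_point[1] + spots$distance_um / ps * cos(theta)
    cy <- caudal_point[2] + spots$distance_um / ps * sin(theta)
    px <- matrix(0, h, w)
    occupied <- matrix(FALSE, h, w)
    entry <- vector("list", nrow(spots))
    for (i in seq_len(nrow(spots))) {
      npx <- round(spots$area_um2[i] / ps^2)
      idx <- disk_pixels(c(cx[i], cy[i]), npx, h, w)
      # require 8-connected separation so components stay distinct
      rr <- (idx - 1L) %% h + 1L; cc <- (idx - 1L) %/% h + 1L
      halo_r <- pmin(pmax(rep(rr, each = 9) +
                            rep(c(-1, 0, 1), times = 3 * length(rr)), 1), h)
      halo_c <- pmin(pmax(rep(cc, each = 9) +
                            rep(rep(c(-1, 0, 1), each = 3), length(cc)), 1), w)
      if (any(occupied[cbind(halo_r, halo_c)]))
        stop("spots overlap or touch", call. = FALSE)
      occupied[idx] <- TRUE
      px[idx] <- intensity
      cen <- c(mean(cc - 0.5), mean(rr - 0.5))
      d_um <- sqrt(sum((cen - caudal_point)^2)) * ps
      entry[[i]] <- list(area_um2 = npx * ps^2,
                         centroid = cen, distance_um = d_um,
                         passes = npx * ps^2 > min_area_um2 &
                           d_um <= max_dist_um)
    }
    px <- add_noise(px, noise_sigma, 255)
    manifest <- list(generator = "spot_image", seed = seed,
                     pixel_size_um = ps, caudal_point = caudal_point,
                     min_area_um2 = min_area_um2,
                     max_dist_um = max_dist_um,
                     spots = entry,
                     truth = list(expected_count =
                                    sum(vapply(entry, `[[`, logical(1),
                                               "passes"))))
    list(image = calibrated_image(px, ps), manifest = manifest)
  })
}

#' Write a fixture manifest as JSON
#'
#' @param manifest Manifest list from a generator.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
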