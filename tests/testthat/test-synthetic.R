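test_that("generators are bit-deterministic under a fixed seed", {
  b <- list(list(colour = c(40, 40, 160), area_um2 = 150,
                 centre = c(100, 100)))
  s1 <- gen_stain_image(b, noise_sigma = 4, seed = 11)
  s2 <- gen_stain_image(b, noise_sigma = 4, seed = 11)
  expect_identical(s1$image$pixels, s2$image$pixels)

  sp <- data.frame(area_um2 = c(60, 80), distance_um = c(120, 300))
  p1 <- gen_spot_image(sp, noise_sigma = 3, seed = 5)
  p2 <- gen_spot_image(sp, noise_sigma = 3, seed = 5)
  expect_identical(p1$image$pixels, p2$image$pixels)
  expect_identical(p1$manifest, p2$manifest)

  cp <- contraction_params(4.4, jitter_sigma_um = 2, seed = 9)
  expect_identical(gen_contraction_pair(cp), gen_contraction_pair(cp))

  w1 <- gen_wound_embryo(small_wound_params(noise_sigma = 5, seed = 2))
  w2 <- gen_wound_embryo(small_wound_params(noise_sigma = 5, seed = 2))
  expect_identical(w1$fluorescence$pixels, w2$fluorescence$pixels)
})

test_that("generators leave the caller's RNG stream untouched", {
  set.seed(123); before <- runif(1)
  set.seed(123)
  invisible(gen_stain_image(list(list(colour = c(0, 0, 200),
                                      area_um2 = 50,
                                      centre = c(50, 50))),
                            noise_sigma = 2, seed = 77))
  expect_identical(runif(1), before)
})

test_that("stain fixtures record exact rasterised blob areas", {
  one <- gen_stain_image(list(list(colour = c(30, 30, 190), area_um2 = 400,
                                   centre = c(120, 150))))
  expect_equal(one$manifest$blobs[[1]]$area_um2, 400)
  expect_equal(one$manifest$truth$stain_area_um2, 400)

  two <- gen_stain_image(list(
    list(colour = c(30, 30, 190), area_um2 = 100, centre = c(80, 80)),
    list(colour = c(30, 30, 190), area_um2 = 300, centre = c(250, 180))))
  expect_equal(two$manifest$truth$stain_area_um2, 400)  # additivity

  art <- gen_stain_image(list(
    list(colour = c(30, 30, 190), area_um2 = 200, centre = c(80, 80)),
    list(colour = c(20, 20, 20), area_um2 = 90, centre = c(250, 180),
         artefact = TRUE)))
  expect_equal(art$manifest$truth$stain_area_um2, 200)

  expect_error(gen_stain_image(list(
    list(colour = c(30, 30, 190), area_um2 = 400, centre = c(100, 100)),
    list(colour = c(200, 0, 0), area_um2 = 400, centre = c(105, 100)))),
    "overlap")
  expect_error(gen_stain_image(list(
    list(colour = c(235, 230, 220), area_um2 = 50,
         centre = c(50, 50)))), "background")
})

test_that("membrane triples sit exactly on their stated circles", {
  cases <- data.frame(radius_um = c(100, 50, NA),
                      bow = c("posterior", "anterior", "straight"))
  tr <- gen_membrane_triples(cases, seed = 3)
  expect_equal(tr[[1]]$kappa_true, 0.01)
  expect_equal(tr[[2]]$kappa_true, -0.02)
  expect_equal(tr[[3]]$kappa_true, 0)
  for (x in tr[1:2]) {
    k <- menger_curvature(x$triple)
    expect_equal(k$kappa, x$kappa_true, tolerance = 1e-12)
  }
  expect_error(
    gen_membrane_triples(data.frame(radius_um = 10, bow = "posterior"),
                         chord_span_um = 40), "half the chord")
})

test_that("contraction pairs encode the configured shortening exactly", {
  same <- gen_contraction_pair(contraction_params(0, seed = 1))
  expect_equal(same$pre, same$post)

  ten <- gen_contraction_pair(contraction_params(10, span_um = 800,
                                                 seed = 1))
  res <- measure_contraction(ten$pre, ten$post)
  expect_equal(res$L_pre_um, 800)
  expect_equal(res$L_post_um, 720)
  expect_equal(res$contraction_percent, 10)
  expect_error(contraction_params(120), "0, 100")
})

test_that("contraction pair files round-trip through CSV", {
  dir <- withr::local_tempdir()
  fx <- gen_contraction_pair(contraction_params(4.4, jitter_sigma_um = 2,
                                                seed = 6), out_dir = dir)
  expect_true(all(file.exists(file.path(dir,
                                        c("pre.csv", "post.csv",
                                          "manifest.json")))))
  res_mem <- measure_contraction(fx$pre, fx$post)
  res_csv <- measure_contraction(read_landmarks(file.path(dir, "pre.csv")),
                                 read_landmarks(file.path(dir, "post.csv")))
  expect_equal(res_csv$contraction_percent, res_mem$contraction_percent)
})

test_that("spot fixtures flag which spots pass the filters", {
  fx <- gen_spot_image(data.frame(area_um2 = c(60, 40, 60),
                                  distance_um = c(100, 200, 600),
                                  angle_deg = c(-30, 20, 5)))
  passes <- vapply(fx$manifest$spots, `[[`, logical(1), "passes")
  expect_equal(passes, c(TRUE, FALSE, FALSE))
  expect_equal(fx$manifest$truth$expected_count, 1)
  # a spot of exactly the threshold area rasterises to exactly 50 px
  ex <- gen_spot_image(data.frame(area_um2 = 50, distance_um = 100,
                                  angle_deg = 0))
  expect_equal(ex$manifest$spots[[1]]$area_um2, 50)
  expect_false(ex$manifest$spots[[1]]$passes)
  expect_error(gen_spot_image(data.frame(area_um2 = c(80, 80),
                                         distance_um = c(100, 101),
                                         angle_deg = c(0, 0))),
               "overlap")
})

test_that("wound fixtures encode their ground-truth score", {
  fx <- gen_wound_embryo(small_wound_params(band_intensity = 200,
                                            basal_intensity = 50))
  expect_equal(fx$manifest$truth$score, 150)
  flat <- gen_wound_embryo(small_wound_params(band_intensity = 60,
                                              basal_intensity = 60))
  expect_equal(flat$manifest$truth$score, 0)
  expect_error(wound_scene_params(band_intensity = 10,
                                  basal_intensity = 50), "band_intensity")
  expect_error(gen_wound_embryo(small_wound_params(band_width_um = 5000)),
               "wider than the embryo")
})

test_that("manifests serialise to JSON", {
  fx <- gen_stain_image(list(list(colour = c(30, 30, 190), area_um2 = 100,
                                  centre = c(80, 80))), seed = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_manifest(fx$manifest, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$truth$stain_area_um2, 100)
  expect_equal(back$seed, 2)
})
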