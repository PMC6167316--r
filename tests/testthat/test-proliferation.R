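test_that("maximum projection is the per-pixel max across slices", {
  one <- calibrated_image(matrix(sample(0:255, 100, TRUE) + 0, 10, 10), 1)
  expect_identical(max_project(list(one))$pixels, one$pixels)

  set.seed(31)
  stack <- lapply(1:5, function(i)
    calibrated_image(matrix(sample(0:255, 12 * 9, TRUE) + 0, 12, 9), 1))
  proj <- max_project(stack)
  # brute-force per-pixel loop oracle
  want <- matrix(0, 12, 9)
  for (r in 1:12) for (c in 1:9)
    want[r, c] <- max(vapply(stack, function(s) s$pixels[r, c], numeric(1)))
  expect_identical(proj$pixels, want)

  small <- calibrated_image(matrix(0, 5, 5), 1)
  expect_error(max_project(list(stack[[1]], small)), "dimensions")
  recal <- calibrated_image(stack[[1]]$pixels, 2)
  expect_error(max_project(list(stack[[1]], recal)), "calibrations")
})

test_that("two disjoint bright disks survive projection", {
  a <- matrix(0, 40, 40); a[5:10, 5:10] <- 200
  b <- matrix(0, 40, 40); b[25:30, 25:30] <- 180
  proj <- max_project(list(calibrated_image(a, 1), calibrated_image(b, 1)))
  expect_equal(sum(proj$pixels > 0), 72)
})

test_that("spot counting applies the strict-area and inclusive-distance filters", {
  fx <- gen_spot_image(data.frame(area_um2 = c(60, 40, 60),
                                  distance_um = c(100, 200, 600),
                                  angle_deg = c(-30, 20, 5)))
  res <- detect_spots(fx$image, spot_filter_params(c(80, 300)))
  expect_equal(res$count, 1)
  expect_equal(nrow(res$spots), 3)

  # a spot of exactly 50 um^2 is excluded (strictly greater than)
  ex <- gen_spot_image(data.frame(area_um2 = 50, distance_um = 100,
                                  angle_deg = 0))
  r2 <- detect_spots(ex$image, spot_filter_params(c(80, 300)))
  expect_equal(r2$spots$area_um2, 50)
  expect_equal(r2$count, 0)
  # but one square micron more is counted
  ok <- gen_spot_image(data.frame(area_um2 = 51, distance_um = 100,
                                  angle_deg = 0))
  expect_equal(detect_spots(ok$image, spot_filter_params(c(80, 300)))$count,
               1)
})

test_that("counts on constructed fields equal the manifest expectation", {
  spots <- data.frame(area_um2 = round(seq(42, 130, length.out = 20)),
                      distance_um = rep(seq(150, 450, length.out = 5), 4),
                      angle_deg = rep(c(-38, -14, 12, 38), each = 5))
  fx <- gen_spot_image(spots, seed = 13)
  res <- detect_spots(fx$image, spot_filter_params(c(80, 300)))
  expect_equal(res$count, fx$manifest$truth$expected_count)
  expect_equal(nrow(res$spots), 20)
  areas <- sort(vapply(fx$manifest$spots, `[[`, numeric(1), "area_um2"))
  expect_equal(sort(res$spots$area_um2), areas)
})

test_that("a blank image yields zero spots, not an error", {
  blank <- calibrated_image(matrix(0, 50, 50), 1)
  expect_equal(detect_spots(blank, spot_filter_params(c(10, 10)))$count, 0L)
})

test_that("the count is monotone in the filter parameters", {
  spots <- data.frame(area_um2 = round(seq(42, 130, length.out = 12)),
                      distance_um = seq(100, 640, length.out = 12),
                      angle_deg = seq(-22, 22, length.out = 12))
  fx <- gen_spot_image(spots, width_um = 900, seed = 3)
  counts_area <- vapply(c(0, 40, 50, 80, 200), function(a)
    detect_spots(fx$image,
                 spot_filter_params(c(80, 300), min_area_um2 = a))$count,
    integer(1))
  expect_true(all(diff(counts_area) <= 0))
  counts_dist <- vapply(c(100, 300, 500, 800, 2000), function(d)
    detect_spots(fx$image,
                 spot_filter_params(c(80, 300), max_dist_um = d))$count,
    integer(1))
  expect_true(all(diff(counts_dist) >= 0))
  # min area 0 and unbounded distance recover the raw component count
  all_of_them <- detect_spots(fx$image,
                              spot_filter_params(c(80, 300),
                                                 min_area_um2 = 0,
                                                 max_dist_um = 1e6))
  expect_equal(all_of_them$count, 12)
})

test_that("translating image and caudal point together preserves counts", {
  spots <- data.frame(area_um2 = c(60, 90), distance_um = c(120, 300),
                      angle_deg = c(-20, 25))
  fx <- gen_spot_image(spots)
  base <- detect_spots(fx$image, spot_filter_params(c(80, 300)))
  shifted <- matrix(0, 600, 800)
  shifted[31:600, 41:800] <- fx$image$pixels[1:570, 1:760]
  res <- detect_spots(calibrated_image(shifted, 1),
                      spot_filter_params(c(80 + 40, 300 + 30)))
  expect_equal(res$count, base$count)
  expect_error(detect_spots(fx$image, spot_filter_params(c(-5, 10))),
               "outside")
})

test_that("an absolute threshold overrides Otsu", {
  m <- matrix(0, 30, 30); m[10:15, 10:15] <- 90   # 36 px at intensity 90
  img <- calibrated_image(m, 1)
  hi <- detect_spots(img, spot_filter_params(c(15, 15), min_area_um2 = 10,
                                             threshold = 100))
  expect_equal(hi$count, 0)
  lo <- detect_spots(img, spot_filter_params(c(15, 15), min_area_um2 = 10,
                                             threshold = 90))
  expect_equal(lo$count, 1)
})
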