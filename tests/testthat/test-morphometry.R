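test_that("a straight membrane scores curvature exactly zero", {
  k <- menger_curvature(membrane_triple(c(0, 0), c(0, 50), c(0, 100), 1))
  expect_identical(k$kappa, 0)
  expect_identical(k$sign, 0L)
  expect_identical(k$radius_um, Inf)
})

test_that("curvature magnitude follows 4A/(abc)", {
  # (0,0), (2,0), (1,1): area 1, sides 2, sqrt2, sqrt2 -> |kappa| = 1
  k <- menger_curvature(membrane_triple(c(0, 0), c(2, 0), c(1, 1), 1))
  expect_equal(abs(k$kappa), 1)
  expect_equal(k$radius_um, 1)
})

test_that("the sign encodes posterior (+) versus anterior (-) bowing", {
  post <- menger_curvature(membrane_triple(c(0, 0), c(0, 100), c(8, 50), 1))
  ant <- menger_curvature(membrane_triple(c(0, 0), c(0, 100), c(-8, 50), 1))
  expect_gt(post$kappa, 0)
  expect_lt(ant$kappa, 0)
  expect_equal(post$kappa, -ant$kappa)
})

test_that("curvature matches an exact circumcircle solver", {
  set.seed(7)
  for (i in 1:200) {
    pts <- matrix(runif(6, 0, 100), 3, 2)
    tr <- membrane_triple(pts[1, ], pts[2, ], pts[3, ], 1)
    k <- menger_curvature(tr)
    R <- oracle_circumradius(pts[1, ], pts[2, ], pts[3, ])
    expect_equal(abs(k$kappa), 1 / R, tolerance = 1e-9)
  }
})

test_that("curvature transforms correctly under similarity maps", {
  set.seed(8)
  for (i in 1:50) {
    pts <- matrix(runif(6, 0, 100), 3, 2)
    k0 <- menger_curvature(membrane_triple(pts[1, ], pts[2, ], pts[3, ], 1))
    s <- runif(1, 0.2, 5)
    ks <- menger_curvature(membrane_triple(pts[1, ] * s, pts[2, ] * s,
                                           pts[3, ] * s, 1))
    expect_equal(abs(ks$kappa), abs(k0$kappa) / s, tolerance = 1e-9)
    d <- runif(2, -50, 50)
    kt <- menger_curvature(membrane_triple(pts[1, ] + d, pts[2, ] + d,
                                           pts[3, ] + d, 1))
    expect_equal(abs(kt$kappa), abs(k0$kappa), tolerance = 1e-9)
    th <- runif(1, 0, 2 * pi)
    Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    kr <- menger_curvature(membrane_triple(as.vector(Rm %*% pts[1, ]),
                                           as.vector(Rm %*% pts[2, ]),
                                           as.vector(Rm %*% pts[3, ]), 1))
    expect_equal(abs(kr$kappa), abs(k0$kappa), tolerance = 1e-9)
    # mirroring about a vertical axis flips anterior and posterior
    mir <- function(p) c(-p[1], p[2])
    km <- menger_curvature(membrane_triple(mir(pts[1, ]), mir(pts[2, ]),
                                           mir(pts[3, ]), 1))
    expect_equal(km$kappa, -k0$kappa, tolerance = 1e-9)
  }
  expect_error(menger_curvature(membrane_triple(c(0, 0), c(0, 0),
                                                c(1, 1), 1)),
               "coincident")
})

test_that("pixel size converts curvature to physical units", {
  k1 <- menger_curvature(membrane_triple(c(0, 0), c(0, 100), c(10, 50), 1))
  k2 <- menger_curvature(membrane_triple(c(0, 0), c(0, 100), c(10, 50), 2))
  expect_equal(k2$kappa, k1$kappa / 2)
})

test_that("axial length is the projection on the body axis", {
  expect_equal(measure_axial_length(c(0, 0), c(100, 0)), 100)
  # perpendicular displacement does not change the measurement
  expect_equal(measure_axial_length(c(0, 0), c(100, 37)), 100)
  u <- c(cos(pi / 6), sin(pi / 6))
  v <- c(-sin(pi / 6), cos(pi / 6))
  end <- 200 * u + 15 * v
  expect_equal(measure_axial_length(c(0, 0), end, axis = u), 200)
  expect_equal(measure_axial_length(c(0, 0), c(100, 0), calibration = 0.5),
               50)
  expect_error(measure_axial_length(c(0, 0), c(1, 1), axis = c(0, 0)),
               "non-zero")
})

test_that("contraction is the relative axial shortening in percent", {
  pre <- data.frame(name = c("somite_01", "somite_08"),
                    x = c(0, 800), y = c(10, 10))
  post <- data.frame(name = c("somite_01", "somite_08"),
                     x = c(0, 764.8), y = c(10, 10))
  res <- measure_contraction(pre, post)
  expect_equal(res$contraction_percent, 4.4)
  expect_equal(measure_contraction(pre, pre)$contraction_percent, 0)
  expect_error(measure_contraction(pre, post[1, , drop = FALSE]),
               "missing from post")
})

test_that("contraction recovery is unbiased under landmark jitter", {
  for (truth in c(4.4, 1.2)) {
    est <- vapply(1:30, function(s) {
      fx <- gen_contraction_pair(
        contraction_params(truth, jitter_sigma_um = 2, seed = s))
      measure_contraction(fx$pre, fx$post)$contraction_percent
    }, numeric(1))
    expect_lt(abs(mean(est) - truth), 0.3)
  }
  # and exact without jitter
  fx <- gen_contraction_pair(contraction_params(4.4, seed = 1))
  expect_equal(measure_contraction(fx$pre, fx$post)$contraction_percent,
               4.4)
})

test_that("bead area delegates to the polygon measurement", {
  sq <- polygon_roi(c(0, 20, 20, 0), c(0, 0, 20, 20))
  expect_equal(bead_area(sq, 1), 400)
  th <- seq(0, 2 * pi, length.out = 33)[-33]
  gon <- polygon_roi(50 * cos(th), 50 * sin(th))
  expect_lt(abs(bead_area(gon, 1) - pi * 50^2) / (pi * 50^2), 0.01)
})

test_that("the measured cell is the spanning one nearest the 600 um line", {
  mk_trace <- function(id, x) data.frame(trace_id = id, x = x,
                                         y = c(0, 20, 40))
  traces <- rbind(mk_trace("a", 420), mk_trace("b", 550),
                  mk_trace("c", 700))
  ann <- data.frame(trace_id = c("a", "b", "c"),
                    spans_band = TRUE, bent = FALSE)
  # stump at x = 1000: distances 580, 450, 300 -> "a" is nearest 600
  sel <- select_measurement_cell(traces, ann, stump_x = 1000)
  expect_equal(sel$trace_id, "a")
  ann$bent <- TRUE
  expect_error(select_measurement_cell(traces, ann, stump_x = 1000),
               "no eligible")
})

test_that("the apex is the chain point furthest from the sheath chord", {
  # membrane sampled from a circle bulging posteriorly
  t_arc <- seq(-0.4, 0.4, length.out = 21)
  chain <- data.frame(trace_id = "m",
                      x = 500 + 60 * cos(t_arc) - 60 * cos(0.4),
                      y = 100 + 60 * sin(t_arc))
  ann <- data.frame(trace_id = "m", spans_band = TRUE, bent = FALSE)
  sel <- select_measurement_cell(chain, ann, stump_x = 900)
  # brute-force scan over chain points
  a <- unlist(chain[1, c("x", "y")]); b <- unlist(chain[21, c("x", "y")])
  u <- (b - a) / sqrt(sum((b - a)^2))
  perp <- abs((chain$x - a[1]) * u[2] - (chain$y - a[2]) * u[1])
  best <- unlist(chain[which.max(perp), c("x", "y")])
  expect_equal(sel$triple$apex, best, ignore_attr = TRUE)
  # and the recovered radius matches the construction
  expect_equal(menger_curvature(sel$triple)$radius_um, 60, tolerance = 1e-6)
})
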