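test_that("noiseless cylinder recovery is exact to numerical tolerance", {
  pts <- cylinder_points(5000, radius = 0.025, length = 0.2)
  f <- fit_cylinder(pts)
  expect_lt(abs(f$radius - 0.025), 1e-9)                 # 1e-6 mm
  expect_lt(acos(min(1, abs(f$axis[3]))) * 180 / pi, 1e-4)
  expect_lt(f$rms, 1e-9)
})

test_that("noisy cylinder fits recover the radius within 2% (95% of seeds)", {
  ok <- 0L
  for (s in 1:100) {
    set.seed(s)
    pts <- cylinder_points(2000, radius = 0.025, length = 0.2, seed = s) +
      matrix(rnorm(6000, 0, 0.002), ncol = 3)
    f <- tryCatch(fit_cylinder(pts), error = function(e) NULL)
    if (!is.null(f) && abs(f$radius - 0.025) / 0.025 < 0.02) ok <- ok + 1L
  }
  expect_gte(ok, 95L)
})

test_that("degenerate inputs are rejected with diagnostics", {
  expect_error(fit_cylinder(matrix(rnorm(9), 3)), "at least 6")
  line <- cbind(seq(0, 1, length.out = 10), 0, 0)
  expect_error(fit_cylinder(line), "collinear")
  plane <- cbind(runif(10), runif(10), 0)
  expect_error(fit_cylinder(plane), "coplanar")
})

test_that("surface coverage counts cells exactly", {
  cyl <- list(start = c(0, 0, 0), axis = c(0, 0, 1), length = 0.2,
              radius = 0.025)
  pts <- cylinder_points(8000, radius = 0.025, length = 0.2)
  expect_equal(surface_coverage(NULL, cyl, 8, 10), 0)
  expect_equal(surface_coverage(pts, cyl, 8, 10), 1)

  # half the azimuth range, even azimuth cell count -> exactly 0.5
  ang <- runif(8000, 0, pi)
  half <- cbind(0.025 * cos(ang), 0.025 * sin(ang), runif(8000, 0, 0.2))
  expect_equal(surface_coverage(half, cyl, 8, 10), 0.5)

  # cell-counting oracle: points placed in known cells
  set.seed(21)
  for (rep in 1:5) {
    na <- sample(2:9, 1); nh <- sample(1:6, 1)
    cells <- unique(cbind(sample(na, 12, TRUE), sample(nh, 12, TRUE)))
    ang <- -pi + (cells[, 1] - 0.5) / na * 2 * pi
    hh <- (cells[, 2] - 0.5) / nh * 0.2
    # azimuth measured in the cylinder frame basis (u = +x for a +Z axis)
    pp <- cbind(0.025 * cos(ang), 0.025 * sin(ang), hh)
    got <- surface_coverage(pp, cyl, na, nh)
    expect_equal(got, nrow(cells) / (na * nh))
  }
})

test_that("model_segment reconstructs straight and curved roots", {
  # straight root, r = 20 mm, length 2 m, dense sampling
  set.seed(22)
  n <- 30000
  ang <- runif(n, 0, 2 * pi)
  x <- runif(n, 0, 2)
  pts <- cbind(x, 0.02 * cos(ang), 0.02 * sin(ang))
  cl <- root_cloud(pts)
  cov <- generate_cover(cl, 20, seed = 1)
  # build one segment spanning all patches, ordered by x of patch centers
  ordp <- order(cov$centers[, 1])
  layers <- split(ordp, cut(cov$centers[ordp, 1], breaks = 100))
  layers <- layers[lengths(layers) > 0]
  seg <- list(id = 1L, layers = unname(layers), parent = NULL)
  cdf <- model_segment(seg, cl, cov)
  expect_lt(abs(sum(cdf$length) - 2) / 2, 0.05)
  expect_true(all(abs(cdf$radius - 0.02) / 0.02 < 0.10))

  # quarter circle, radius of curvature 1 m
  t <- runif(n, 0, pi / 2)
  ctr <- cbind(cos(t), sin(t), 0)
  nrm <- cbind(cos(t), sin(t), 0)
  binv <- matrix(c(0, 0, 1), n, 3, byrow = TRUE)
  pts2 <- ctr + 0.02 * (cos(ang) * nrm + sin(ang) * binv)
  # re-center to start at origin-ish
  cl2 <- root_cloud(pts2)
  cov2 <- generate_cover(cl2, 20, seed = 1)
  ordp2 <- order(atan2(cov2$centers[, 2], cov2$centers[, 1]))
  lay2 <- split(ordp2, cut(seq_along(ordp2), 80))
  seg2 <- list(id = 1L, layers = unname(lay2[lengths(lay2) > 0]),
               parent = NULL)
  cdf2 <- model_segment(seg2, cl2, cov2)
  expect_gte(nrow(cdf2), 4L)
  ax <- as.matrix(cdf2[, c("axis_x", "axis_y", "axis_z")])
  cosang <- rowSums(ax[-1, , drop = FALSE] * ax[-nrow(ax), , drop = FALSE])
  expect_true(all(acos(pmin(1, cosang)) < 45 * pi / 180))

  # empty segment
  expect_equal(nrow(model_segment(list(id = 1, layers = list()), cl, cov)),
               0L)
})

test_that("selected cylinders dominate rejected candidates by coverage", {
  # re-run a window selection manually: the emitted coverage must be the max
  sc <- small_scan()
  qsm <- suppressWarnings(build_qsm(sc$cloud, 25, seed = 2))
  expect_true(all(qsm$cylinders$coverage >= 0 & qsm$cylinders$coverage <= 1))
  expect_true(all(qsm$cylinders$length > 0))
  expect_true(all(qsm$cylinders$radius > 0))
  # volume identity against an independent summation
  v <- 0
  for (i in seq_len(nrow(qsm$cylinders)))
    v <- v + pi * qsm$cylinders$radius[i]^2 * qsm$cylinders$length[i]
  expect_equal(qsm_volume(qsm), v, tolerance = 1e-12)
})

test_that("taproot-only clouds give a single order-0 chain", {
  tap <- taproot_scan()
  qsm <- suppressWarnings(build_qsm(tap$cloud, 25, seed = 1))
  expect_true(all(qsm$cylinders$order == 0L))
  tr <- compute_traits(qsm)
  expect_equal(unname(tr$totals["number"]), 0)
})

test_that("build_qsm is deterministic given identical inputs and seed", {
  sc <- small_scan()
  q1 <- suppressWarnings(build_qsm(sc$cloud, 25, seed = 3))
  q2 <- suppressWarnings(build_qsm(sc$cloud, 25, seed = 3))
  expect_identical(q1, q2)
})

test_that("dense occlusion-free scans recover total volume at the optimum", {
  sc <- small_scan()
  tt <- truth_traits(sc$truth)
  # noiseless, occlusion-free, fine scan of the same 2-root system
  cloud <- scan_system(sc$truth,
                       scanner_spec(angular_step_deg = 0.04, range_m = 4,
                                    range_noise_mm = 0, occlusion = FALSE,
                                    seed = 1))
  grid <- c(10, 15, 20, 25, 30)
  sw <- suppressWarnings(sweep_patchdiam(cloud, grid = grid, seeds = 1L))
  best <- which.min(abs(sw$means$volume - tt$totals["volume_dm3"]))
  expect_lt(abs(sw$means$volume[best] - tt$totals["volume_dm3"]) /
              tt$totals["volume_dm3"], 0.10)
})
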