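test_that("spec validation rejects inconsistent parameters", {
  expect_error(root_system_spec(asymmetry = c(N = 1, E = 1, S = 0, W = 0) / 1),
               "sum to 1")
  expect_error(root_system_spec(taper = 1), "taper")
  expect_error(root_system_spec(first_radius = c(-1, 1)), "positive")
})

test_that("a lateral-free spec yields a taproot-only system", {
  truth <- generate_system(root_system_spec(n_first = 0L, seed = 2))
  expect_equal(nrow(truth$roots), 1L)
  tt <- truth_traits(truth)
  expect_equal(unname(tt$totals["length_m"]), 0)
  expect_equal(unname(tt$totals["number"]), 0)
})

test_that("analytic truth traits match the stated closed form", {
  spec <- root_system_spec(n_first = 5L, first_radius = c(0.02, 0.02),
                           first_length = c(1.5, 1.5), taper = 0,
                           second_per_first = 0, third_per_second = 0,
                           curvature = 0, seed = 9)
  tt <- truth_traits(generate_system(spec))
  expect_equal(unname(tt$totals["length_m"]), 7.5, tolerance = 1e-9)
  expect_equal(unname(tt$totals["volume_dm3"]), 5 * pi * 0.02^2 * 1.5 * 1000,
               tolerance = 1e-9)
  expect_equal(unname(tt$totals["number"]), 5)
})

test_that("truth traits equal a brute-force summation over cylinders", {
  truth <- generate_system(root_system_spec(seed = 6))
  tt <- truth_traits(truth)
  # independent loop over generative cylinders
  len <- vol <- 0
  counted <- character(0)
  for (i in seq_len(nrow(truth$cylinders))) {
    cy <- truth$cylinders[i, ]
    if (cy$order == 0L) next
    rid <- cy$root_id
    if (200 * truth$polylines[[rid]]$radii[1] < 1) next
    len <- len + cy$length
    vol <- vol + pi * cy$radius^2 * cy$length * 1000
    counted <- union(counted, as.character(rid))
  }
  expect_equal(unname(tt$totals["length_m"]), len, tolerance = 1e-12)
  expect_equal(unname(tt$totals["volume_dm3"]), vol, tolerance = 1e-12)
  expect_equal(unname(tt$totals["number"]), length(counted))
})

test_that("azimuthal asymmetry follows the quadrant weights", {
  spec <- root_system_spec(n_first = 200L, second_per_first = 0,
                           third_per_second = 0,
                           asymmetry = c(N = 0.7, E = 0.1, S = 0.1, W = 0.1),
                           seed = 10)
  tt <- truth_traits(generate_system(spec))
  nN <- tt$by_quadrant$number[tt$by_quadrant$quadrant == "N"]
  ci <- qbinom(c(0.005, 0.995), 200, 0.7)
  expect_gte(nN, ci[1])
  expect_lte(nN, ci[2])
})

test_that("single-viewpoint scans cover about half the surface", {
  spec <- root_system_spec(n_first = 0L, taproot_depth = 0.5,
                           taproot_radius = 0.04, curvature = 0, seed = 3)
  truth <- generate_system(spec)
  cloud <- scan_system(truth, scanner_spec(n_viewpoints = 1L, range_m = 4,
                                           range_noise_mm = 0,
                                           angular_step_deg = 0.05, seed = 1))
  cyl <- list(start = c(0, 0, 0), axis = c(0, 0, -1), length = 0.5,
              radius = truth$cylinders$radius[1])
  cov <- surface_coverage(cloud$points, cyl, 16, 10)
  expect_gt(cov, 0.35)
  expect_lt(cov, 0.6)
})

test_that("noiseless scans lie exactly on the generative surfaces", {
  spec <- root_system_spec(n_first = 0L, taproot_depth = 0.5,
                           taproot_radius = 0.04, curvature = 0, seed = 3)
  truth <- generate_system(spec)
  cloud <- scan_system(truth, scanner_spec(range_m = 4, range_noise_mm = 0,
                                           angular_step_deg = 0.05, seed = 1))
  cyl <- truth$cylinders[cloud$labels$cyl_id, ]
  rel <- cloud$points - as.matrix(cyl[, c("start_x", "start_y", "start_z")])
  t <- rowSums(rel * as.matrix(cyl[, c("axis_x", "axis_y", "axis_z")]))
  daxis <- sqrt(pmax(rowSums(rel^2) - t^2, 0))
  expect_lt(max(abs(daxis - cyl$radius)), 1e-9)
})

test_that("range noise displaces points consistently with its sd", {
  spec <- root_system_spec(n_first = 0L, taproot_depth = 0.5,
                           taproot_radius = 0.04, curvature = 0, seed = 3)
  truth <- generate_system(spec)
  cloud <- scan_system(truth, scanner_spec(range_m = 4, range_noise_mm = 2,
                                           angular_step_deg = 0.05, seed = 1))
  cyl <- truth$cylinders[cloud$labels$cyl_id, ]
  rel <- cloud$points - as.matrix(cyl[, c("start_x", "start_y", "start_z")])
  t <- rowSums(rel * as.matrix(cyl[, c("axis_x", "axis_y", "axis_z")]))
  daxis <- sqrt(pmax(rowSums(rel^2) - t^2, 0))
  dsurf <- abs(daxis - cyl$radius)
  expect_gte(mean(dsurf <= 0.004), 0.95)
})

test_that("digitization step counts follow the curved/straight rule", {
  straight <- root_system_spec(n_first = 1L, first_length = c(1.5, 1.5),
                               first_radius = c(0.02, 0.02), curvature = 0,
                               second_per_first = 0, third_per_second = 0,
                               seed = 4)
  rec <- digitize_system(generate_system(straight))
  lateral <- rec$points[rec$points$root_id == 2L, ]
  expect_equal(nrow(lateral), 11L)                    # 1.5 m / 0.15 m + 1

  curved <- root_system_spec(n_first = 1L, first_length = c(0.2, 0.2),
                             first_radius = c(0.02, 0.02), curvature = 1,
                             second_per_first = 0, third_per_second = 0,
                             seed = 4)
  rec2 <- digitize_system(generate_system(curved))
  lateral2 <- rec2$points[rec2$points$root_id == 2L, ]
  expect_equal(nrow(lateral2), 11L)                   # 0.2 m / 0.02 m + 1
})

test_that("scan_system and digitize_system are deterministic per seed", {
  spec <- root_system_spec(seed = 8)
  t1 <- generate_system(spec)
  t2 <- generate_system(spec)
  expect_identical(t1, t2)
  sc <- scanner_spec(angular_step_deg = 0.15, seed = 8)
  expect_identical(scan_system(t1, sc), scan_system(t2, sc))
  expect_identical(digitize_system(t1), digitize_system(t2))
})
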