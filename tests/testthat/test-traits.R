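test_that("centrifugal orders follow the parent chain and lump above 3", {
  q <- toy_qsm(with_lateral = TRUE)
  # extend with a third- and fourth-order chain
  q$segments <- rbind(q$segments,
                      data.frame(id = 4L, parent = 3L, n_patches = 0L,
                                 path_length = 1, chord = 1, order = NA),
                      data.frame(id = 5L, parent = 4L, n_patches = 0L,
                                 path_length = 1, chord = 1, order = NA))
  q$cylinders <- rbind(q$cylinders,
    within(q$cylinders[2, ], { segment <- 4L; id <- 3L; parent <- 2L }),
    within(q$cylinders[2, ], { segment <- 5L; id <- 4L; parent <- 3L }))
  qo <- assign_orders(q)
  expect_equal(qo$segments$order, c(0L, 1L, 2L, 3L, 3L))
  qn <- assign_orders(q, lump = FALSE)
  expect_equal(qn$segments$order, c(0L, 1L, 2L, 3L, 4L))

  # cycle detection
  qc <- q
  qc$segments$parent[2] <- 3L
  expect_error(assign_orders(qc), "cycle")
})

test_that("trait table matches the analytic single-root case", {
  tr <- compute_traits(toy_qsm())
  expect_equal(unname(tr$totals["length_m"]), 2)
  expect_equal(unname(tr$totals["volume_dm3"]), pi * 0.02^2 * 2 * 1000,
               tolerance = 1e-12)
  expect_equal(unname(tr$totals["number"]), 1)
  expect_equal(tr$by_quadrant$length_m, c(2, 0, 0, 0))        # all north
  expect_equal(tr$by_depth$length_m, c(2, 0))                 # all shallow
})

test_that("trait table matches the hand-summed two-root case", {
  tr <- compute_traits(toy_qsm(with_lateral = TRUE))
  expect_equal(unname(tr$totals["length_m"]), 3)
  expect_equal(unname(tr$totals["volume_dm3"]),
               (pi * 0.02^2 * 2 + pi * 0.01^2 * 1) * 1000, tolerance = 1e-12)
  expect_equal(tr$by_order$length_m[1:2], c(2, 1))
  expect_equal(tr$by_order$volume_dm3[1:2],
               c(pi * 0.02^2 * 2, pi * 0.01^2 * 1) * 1000, tolerance = 1e-9)
  expect_equal(tr$by_order$number[1:2], c(1L, 1L))
})

test_that("roots below the proximal-diameter filter are excluded", {
  q <- toy_qsm()
  q$cylinders$radius <- 0.004                     # 0.8 cm proximal diameter
  tr <- compute_traits(q)
  expect_equal(unname(tr$totals["number"]), 0)
  expect_equal(unname(tr$totals["length_m"]), 0)
  expect_equal(unname(tr$totals["volume_dm3"]), 0)
  tr2 <- compute_traits(q, min_proximal_diam = 0.5)
  expect_equal(unname(tr2$totals["number"]), 1)
})

test_that("quadrant and order marginals sum exactly to totals", {
  sc <- small_scan()
  qsm <- suppressWarnings(build_qsm(sc$cloud, 25, seed = 1))
  tr <- compute_traits(qsm)
  for (col in c("length_m", "volume_dm3", "number")) {
    expect_equal(sum(tr$by_quadrant[[col]]), unname(tr$totals[col]),
                 tolerance = 1e-9)
    expect_equal(sum(tr$by_order[[col]]), unname(tr$totals[col]),
                 tolerance = 1e-9)
    expect_equal(sum(tr$by_depth[[col]]), unname(tr$totals[col]),
                 tolerance = 1e-9)
  }
})

test_that("a 90-degree rotation about Z permutes quadrants N->W->S->E", {
  sc <- small_scan()
  qsm <- suppressWarnings(build_qsm(sc$cloud, 25, seed = 1))
  tr <- compute_traits(qsm)
  rot <- function(q) {
    cyl <- q$cylinders
    # rotate +90 degrees about Z: (x, y) -> (-y, x)
    for (pre in c("start", "axis")) {
      x <- cyl[[paste0(pre, "_x")]]
      y <- cyl[[paste0(pre, "_y")]]
      cyl[[paste0(pre, "_x")]] <- -y
      cyl[[paste0(pre, "_y")]] <- x
    }
    q$cylinders <- cyl
    q
  }
  tr2 <- compute_traits(rot(qsm))
  perm <- c(N = "W", E = "N", S = "E", W = "S")   # new quadrant of old mass
  for (col in c("length_m", "volume_dm3", "number")) {
    old <- setNames(tr$by_quadrant[[col]], tr$by_quadrant$quadrant)
    new <- setNames(tr2$by_quadrant[[col]], tr2$by_quadrant$quadrant)
    expect_equal(unname(new[perm[names(old)]]), unname(old),
                 tolerance = 1e-9)
    expect_equal(sum(new), sum(old), tolerance = 1e-9)
  }
  # volume invariant under the rigid transform
  expect_equal(unname(tr2$totals["volume_dm3"]),
               unname(tr$totals["volume_dm3"]), tolerance = 1e-12)
})

test_that("trait CSV export is readable and complete", {
  p <- withr::local_tempfile(fileext = ".csv")
  export_traits(compute_traits(toy_qsm(TRUE)), p)
  df <- read.csv(p)
  expect_true(all(c("trait", "order", "quadrant", "depth", "value",
                    "units") %in% names(df)))
  expect_equal(df$value[df$trait == "length_m" & df$order == "all" &
                          df$quadrant == "all" & df$depth == "all"], 3)
})
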