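test_that("find_stump selects the collar region of a taproot", {
  tap <- taproot_scan()
  cov <- generate_cover(tap$cloud, 25, seed = 1)
  stump <- find_stump(cov, tap$cloud)
  expect_gt(length(stump), 0)
  h <- sqrt(rowSums(cov$centers[stump, 1:2, drop = FALSE]^2))
  expect_true(all(h <= 1.5 * 1.3 * 0.06 + 0.03))  # within the stump cylinder
  # explicit radius: centroids within 100 mm of the axis
  stump2 <- find_stump(cov, tap$cloud, radius = 0.1)
  h2 <- sqrt(rowSums(cov$centers[stump2, 1:2, drop = FALSE]^2))
  expect_true(all(h2 <= 0.1))
})

test_that("root bases: none on a bare taproot, one per lateral on a Y", {
  tap <- taproot_scan()
  cov <- generate_cover(tap$cloud, 25, seed = 1)
  stump <- find_stump(cov, tap$cloud)
  bases <- suppressWarnings(detect_root_bases(cov, stump, tap$cloud))
  expect_equal(length(bases), 0L)

  sc <- small_scan()    # taproot + 2 well-separated first-order roots
  cov2 <- generate_cover(sc$cloud, 25, seed = 1)
  stump2 <- find_stump(cov2, sc$cloud)
  bases2 <- suppressWarnings(detect_root_bases(cov2, stump2, sc$cloud))
  expect_equal(length(bases2), 2L)
  for (b in bases2) {
    expect_gt(length(b$patches), 0)
    expect_gt(b$radius, 0)
  }
})

test_that("stump/taproot patches match generator truth labels", {
  sc <- small_scan()
  cov <- generate_cover(sc$cloud, 25, seed = 1)
  stump <- find_stump(cov, sc$cloud)
  bases <- suppressWarnings(detect_root_bases(cov, stump, sc$cloud))
  segs <- segment_roots(cov, bases, stump)
  # segment 1 = stump + taproot continuation; compare with order-0 labels
  tap_patches <- unlist(segs$segments[[1]]$layers)
  tap_points <- unlist(cov$patches[tap_patches])
  truth_points <- which(sc$cloud$labels$order == 0L)
  jac <- length(intersect(tap_points, truth_points)) /
    length(union(tap_points, truth_points))
  expect_gte(jac, 0.8)
})

test_that("segmentation assigns each patch at most once and chains validly", {
  sc <- small_scan()
  cov <- generate_cover(sc$cloud, 25, seed = 1)
  stump <- find_stump(cov, sc$cloud)
  bases <- suppressWarnings(detect_root_bases(cov, stump, sc$cloud))
  segs <- segment_roots(cov, bases, stump)
  all_patches <- unlist(lapply(segs$segments, function(s) unlist(s$layers)))
  expect_equal(anyDuplicated(all_patches), 0L)
  expect_equal(length(all_patches) + segs$n_unassigned, cov$n_patches)
  # consecutive layers are cover-adjacent
  for (s in segs$segments[1:min(5, length(segs$segments))]) {
    if (length(s$layers) < 2) next
    for (k in 2:length(s$layers)) {
      nb <- unique(unlist(cov$adjacency[s$layers[[k - 1]]]))
      expect_true(all(s$layers[[k]] %in% nb))
    }
    expect_lte(s$chord, s$path_length + 1e-9)
  }
})

test_that("two counted roots are recovered on the two-root system", {
  sc <- small_scan()
  qsm <- suppressWarnings(build_qsm(sc$cloud, 25, seed = 1))
  tr <- compute_traits(qsm)
  expect_equal(tr$by_order$number[tr$by_order$order == 1], 2)
})

test_that("base detection recovers well-separated roots across PatchDiam", {
  sc <- small_scan()
  clean <- scan_system(sc$truth,
                       scanner_spec(angular_step_deg = 0.06, range_m = 4,
                                    range_noise_mm = 0, occlusion = FALSE,
                                    seed = 2))
  for (pd in c(10, 20, 30)) {
    cov <- generate_cover(clean, pd, seed = 1)
    stump <- find_stump(cov, clean)
    bases <- suppressWarnings(detect_root_bases(cov, stump, clean))
    expect_equal(length(bases), 2L,
                 label = sprintf("base count at PatchDiam %g", pd))
  }
})

# helper: synthetic segmentation of straight chains for merge tests
chain_segmentation <- function(dirs, n_layers = 6, step = 0.05) {
  segs <- list()
  start <- c(0, 0, 0)
  for (i in seq_along(dirs)) {
    ctrs <- t(sapply(0:(n_layers - 1), function(k) start + k * step * dirs[[i]]))
    segs[[i]] <- list(id = i, layers = as.list(seq_len(n_layers) +
                                                 (i - 1) * n_layers),
                      parent = if (i == 1) NULL else i - 1L,
                      branch_patch = if (i == 1) NULL else (i - 1) * n_layers,
                      layer_ctrs = ctrs,
                      path_length = (n_layers - 1) * step,
                      chord = (n_layers - 1) * step)
    start <- start + (n_layers - 1) * step * dirs[[i]]
  }
  list(segments = segs, n_unassigned = 0L)
}

test_that("collinear segments merge; right-angle segments do not", {
  coll <- chain_segmentation(list(c(1, 0, 0), c(1, 0, 0)))
  m <- merge_segments(coll, straightness = 0.9)
  expect_equal(length(m$segments), 1L)
  expect_equal(m$segments[[1]]$chord / m$segments[[1]]$path_length, 1,
               tolerance = 1e-9)

  bent <- chain_segmentation(list(c(1, 0, 0), c(0, 1, 0)))
  m2 <- merge_segments(bent, straightness = 0.9)
  expect_equal(length(m2$segments), 2L)
  # merged chord/path would be about 0.707, below the 0.9 default
  r <- rootqsm:::.merged_ratio(bent$segments[[1]], bent$segments[[2]])
  expect_lt(abs(r - sqrt(2) * 5.5 / 11), 0.05)
})

test_that("merging reaches a fixed point (idempotent)", {
  set.seed(31)
  for (rep in 1:10) {
    k <- sample(2:5, 1)
    dirs <- lapply(seq_len(k), function(i)
      rootqsm:::.unit(c(1, rnorm(1, 0, 0.4), rnorm(1, 0, 0.4))))
    segm <- chain_segmentation(dirs)
    m1 <- merge_segments(segm)
    m2 <- merge_segments(m1)
    expect_equal(length(m2$segments), length(m1$segments))
    expect_equal(vapply(m2$segments, function(s) s$path_length, 0),
                 vapply(m1$segments, function(s) s$path_length, 0),
                 tolerance = 1e-12)
  }
})
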