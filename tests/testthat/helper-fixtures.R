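# Shared fixtures, built lazily and cached for the whole test run.

.fixtures <- new.env(parent = emptyenv())

# exact points on a cylinder surface (axis +Z through origin)
cylinder_points <- function(n = 5000, radius = 0.025, length = 0.2,
                            seed = 42) {
  set.seed(seed)
  ang <- runif(n, 0, 2 * pi)
  h <- runif(n, 0, length)
  cbind(radius * cos(ang), radius * sin(ang), h)
}

# a small scanned root system (taproot + 2 first-order roots), coarse scan
small_scan <- function() {
  if (is.null(.fixtures$small)) {
    spec <- root_system_spec(taproot_depth = 0.6, taproot_radius = 0.05,
                             n_first = 2L, first_radius = c(0.02, 0.025),
                             first_length = c(0.5, 0.6),
                             second_per_first = 0, third_per_second = 0,
                             curvature = 0.2, seed = 7)
    truth <- generate_system(spec)
    cloud <- scan_system(truth, scanner_spec(angular_step_deg = 0.08,
                                             range_m = 4, seed = 7))
    .fixtures$small <- list(truth = truth, cloud = cloud)
  }
  .fixtures$small
}

# taproot-only system and scan
taproot_scan <- function() {
  if (is.null(.fixtures$tap)) {
    spec <- root_system_spec(taproot_depth = 0.6, taproot_radius = 0.05,
                             n_first = 0L, curvature = 0.1, seed = 3)
    truth <- generate_system(spec)
    cloud <- scan_system(truth, scanner_spec(angular_step_deg = 0.08,
                                             range_m = 4, seed = 3))
    .fixtures$tap <- list(truth = truth, cloud = cloud)
  }
  .fixtures$tap
}

# a hand-built QSM object for trait tests: one first-order root along +X at
# depth 0.1 m (r = 20 mm, l = 2 m), optionally with a second-order lateral
toy_qsm <- function(with_lateral = FALSE) {
  cyl <- data.frame(
    start_x = 0, start_y = 0, start_z = -0.1,
    axis_x = 1, axis_y = 0, axis_z = 0,
    length = 2, radius = 0.02, coverage = 1,
    segment = 2L, id = 1L, parent = NA_integer_, order = 1L)
  segs <- data.frame(id = c(1L, 2L), parent = c(NA_integer_, 1L),
                     n_patches = c(0L, 0L), path_length = c(0, 2),
                     chord = c(0, 2), order = c(0L, 1L))
  if (with_lateral) {
    cyl <- rbind(cyl, data.frame(
      start_x = 1, start_y = 0, start_z = -0.1,
      axis_x = 0, axis_y = -1, axis_z = 0,
      length = 1, radius = 0.01, coverage = 1,
      segment = 3L, id = 2L, parent = 1L, order = 2L))
    segs <- rbind(segs, data.frame(id = 3L, parent = 2L, n_patches = 0L,
                                   path_length = 1, chord = 1, order = 2L))
  }
  structure(list(cylinders = cyl, segments = segs,
                 provenance = list(patch_diam = 20, seed = 1L,
                                   config_hash = "0", n_patches = 0L,
                                   n_unassigned = 0L)),
            class = "root_qsm")
}

# synthetic cover built directly from an adjacency list (for graph ops)
fake_cover <- function(adjacency) {
  structure(list(patch_diam = 10, assignment = integer(0),
                 patches = vector("list", length(adjacency)),
                 centers = matrix(0, length(adjacency), 3),
                 adjacency = lapply(adjacency, as.integer),
                 n_patches = length(adjacency), seed = 1L,
                 adjacency_factor = 1, n_bridged = 0L),
            class = "root_cover")
}
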