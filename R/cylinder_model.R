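#' Least-squares cylinder fit
#'
#' Fits an infinite cylinder by Gauss-Newton minimization of
#' `sum((distance_to_axis - radius)^2)` over axis position, axis direction and
#' radius, initialized from `initial_axis` or the largest principal component
#' of the points. Iterates until the relative parameter change falls below
#' `tol` or `max_iter` iterations.
#'
#' @param points numeric N x 3 matrix (m), N >= 6, not collinear or coplanar.
#' @param initial_axis optional 3-vector initial axis direction.
#' @param max_iter,tol Gauss-Newton controls.
#' @return list: `point` (axis point nearest the centroid), `axis` (unit
#'   vector), `radius` (m), `rms` (m), `iterations`, `converged`.
#' @export
fit_cylinder <- function(points, initial_axis = NULL, max_iter = 100L,
                         tol = 1e-8) {
  points <- as.matrix(points)
  if (nrow(points) < 6L)
    stop("cylinder fit needs at least 6 points", call. = FALSE)
  ctr <- colMeans(points)
  cen <- sweep(points, 2, ctr)
  sv <- svd(cen, nu = 0)
  if (sv$d[2] < 1e-9 * sv$d[1])
    stop("degenerate geometry: points are collinear", call. = FALSE)
  if (sv$d[3] < 1e-9 * sv$d[1])
    stop("degenerate geometry: points are coplanar", call. = FALSE)
  init <- if (is.null(initial_axis)) sv$v[, 1] else .unit(initial_axis)
  fit <- cpp_fit_cylinder(points, init, as.integer(max_iter), tol)
  if (!fit$converged || !all(is.finite(c(fit$point, fit$axis, fit$radius))) ||
      fit$radius <= 0)
    stop(sprintf("cylinder fit diverged after %d iterations (rms %.3g)",
                 fit$iterations, fit$rms), call. = FALSE)
  list(point = as.numeric(fit$point), axis = as.numeric(fit$axis),
       radius = fit$radius, rms = fit$rms, iterations = fit$iterations,
       converged = fit$converged)
}

# robust internal variant: falls back to a PCA axis + median radial distance
# when the least-squares fit fails or is wildly inconsistent with the window
.fit_cylinder_robust <- function(points, initial_axis = NULL) {
  ctr <- colMeans(points)
  cen <- sweep(points, 2, ctr)
  extent <- sqrt(max(rowSums(cen^2)))
  fit <- tryCatch(fit_cylinder(points, initial_axis), error = function(e) NULL)
  if (!is.null(fit) && fit$radius <= 2 * extent) return(fit)
  sv <- svd(cen, nu = 0)
  axis <- if (is.null(initial_axis)) sv$v[, 1] else .unit(initial_axis)
  t <- as.vector(cen %*% axis)
  rad <- sqrt(pmax(rowSums(cen^2) - t^2, 0))
  r <- stats::median(rad)
  if (!is.finite(r) || r <= 0) r <- max(1e-4, extent / 4)
  list(point = ctr, axis = axis, radius = r,
       rms = sqrt(mean((rad - r)^2)), iterations = 0L, converged = FALSE)
}

#' Surface coverage of a cylinder by points
#'
#' The cylinder-selection statistic: points are projected into the cylinder
#' frame, those with height in `[0, length]` are binned into an
#' azimuth x height cell grid, and coverage is the fraction of non-empty
#' cells.
#'
#' @param points numeric N x 3 matrix (m); may be empty.
#' @param cylinder list with `start` (3-vector), `axis` (unit 3-vector),
#'   `length` (m), `radius` (m).
#' @param n_azimuth,n_height cell counts (>= 1).
#' @return fraction in `[0, 1]`.
#' @export
surface_coverage <- function(points, cylinder, n_azimuth = 8L,
                             n_height = 4L) {
  n_azimuth <- max(1L, as.integer(n_azimuth))
  n_height <- max(1L, as.integer(n_height))
  if (is.null(points) || NROW(points) == 0L) return(0)
  points <- as.matrix(points)
  b <- .perp_basis(cylinder$axis)
  y <- sweep(points, 2, as.numeric(cylinder$start))
  h <- as.vector(y %*% b$w)
  keep <- h >= 0 & h <= cylinder$length
  if (!any(keep)) return(0)
  y <- y[keep, , drop = FALSE]
  h <- h[keep]
  az <- atan2(as.vector(y %*% b$v), as.vector(y %*% b$u))  # (-pi, pi]
  ia <- pmin(n_azimuth, floor((az + pi) / (2 * pi) * n_azimuth) + 1L)
  ih <- pmin(n_height, floor(h / cylinder$length * n_height) + 1L)
  length(unique((ih - 1L) * n_azimuth + ia)) / (n_azimuth * n_height)
}

# number of height cells used when evaluating a cylinder of length len (m)
# at resolution patch_diam (mm)
.n_height_cells <- function(len, patch_diam) {
  max(1L, as.integer(round(len / (patch_diam / 1000))))
}

#' Model one segment as a chain of cylinders
#'
#' Walks a segment from base to tip. At each position candidate cylinders of
#' length `multipliers * patch_diam` over the points ahead are fitted (each
#' fit re-initialized from the previous cylinder's direction, adapting to
#' local curvature) and scored by [surface_coverage()]; the highest-coverage
#' candidate is emitted (ties broken toward the longer candidate) and the
#' walk advances past it. Consecutive cylinders share endpoints. Windows with
#' fewer than 6 points are extended to the next candidate length; a tip
#' remainder shorter than the smallest candidate is absorbed into the final
#' cylinder.
#'
#' @param segment a segment from [segment_roots()] (list with `layers`).
#' @param cloud the [root_cloud()].
#' @param cover the [generate_cover()] used for segmentation.
#' @param multipliers candidate lengths as multiples of `patch_diam`.
#' @param n_azimuth azimuthal cell count for the coverage statistic.
#' @return data.frame of cylinders (start, axis, length, radius, coverage).
#' @export
model_segment <- function(segment, cloud, cover, multipliers = c(2, 3, 4, 6),
                          n_azimuth = 8L) {
  layers <- segment$layers
  if (length(layers) == 0L) return(.empty_cylinders())
  pd_m <- cover$patch_diam / 1000
  cand_len <- sort(multipliers) * pd_m
  layer_pts <- lapply(layers, function(ids)
    cloud$points[unlist(cover$patches[ids], use.names = FALSE), , drop = FALSE])
  nlay <- length(layers)
  lay_ctr <- t(vapply(layer_pts, colMeans, numeric(3)))

  out <- list()
  li <- 1L
  prev_end <- NULL
  prev_axis <- NULL
  while (li <= nlay) {
    base_pt <- if (is.null(prev_end)) lay_ctr[li, ] else prev_end
    # cumulative distance of each remaining layer centroid from the window base
    rem <- li:nlay
    dists <- sqrt(rowSums(sweep(lay_ctr[rem, , drop = FALSE], 2, base_pt)^2))
    best <- NULL
    for (ci in seq_along(cand_len)) {
      L <- cand_len[ci]
      take <- rem[dists <= L + pd_m / 2]
      if (length(take) == 0L) take <- rem[1L]
      pts <- do.call(rbind, layer_pts[take])
      if (nrow(pts) < 6L && ci < length(cand_len)) next
      if (nrow(pts) < 6L) { take <- rem; pts <- do.call(rbind, layer_pts[take]) }
      if (nrow(pts) < 6L) break
      fit <- .fit_cylinder_robust(pts, prev_axis)
      axis <- fit$axis
      # orient toward the tip: use a layer a little ahead of the window,
      # which is robust when the window spans a single layer
      ref <- rem[min(length(rem), max(length(take) + 1L, 4L))]
      tipdir <- lay_ctr[ref, ] - base_pt
      if (sqrt(sum(tipdir^2)) < 1e-9 && !is.null(prev_axis))
        tipdir <- prev_axis
      if (sum(axis * tipdir) < 0) axis <- -axis
      start <- base_pt
      proj <- as.vector(sweep(pts, 2, start) %*% axis)
      if (is.null(prev_end)) {
        # segment base: extend backward to cover the window's rear points
        back <- min(proj)
        if (back < 0) {
          start <- start + back * axis
          proj <- proj - back
        }
      }
      len <- max(proj)
      if (len <= 1e-6) len <- max(L / 2, 1e-3)
      cyl <- list(start = start, axis = axis, length = len,
                  radius = fit$radius)
      covg <- surface_coverage(pts, cyl, n_azimuth,
                               .n_height_cells(len, cover$patch_diam))
      if (is.null(best) || covg > best$coverage + 1e-12 ||
          (abs(covg - best$coverage) <= 1e-12 && len > best$length)) {
        best <- list(cyl = cyl, coverage = covg, take = take, length = len)
      }
    }
    if (is.null(best)) {
      # too few points even over the whole remainder: absorb into previous
      if (length(out)) {
        pts <- do.call(rbind, layer_pts[rem])
        last <- out[[length(out)]]
        proj <- as.vector(sweep(pts, 2, last$start) %*% last$axis)
        out[[length(out)]]$length <- max(last$length, max(proj))
      }
      break
    }
    cyl <- best$cyl
    # consume layers whose centroid projects inside the accepted cylinder
    # (not those behind it, which a misoriented fit would otherwise eat)
    projc <- as.vector(sweep(lay_ctr[rem, , drop = FALSE], 2, cyl$start) %*%
                         cyl$axis)
    consumed <- rem[projc <= cyl$length + 1e-9 & projc >= -pd_m]
    if (length(consumed) == 0L) consumed <- rem[1L]
    li2 <- max(consumed) + 1L
    # tip remainder shorter than the smallest candidate: absorb it
    if (li2 <= nlay) {
      tail_d <- sqrt(sum((lay_ctr[nlay, ] - (cyl$start + cyl$axis *
                                               cyl$length))^2))
      if (tail_d < cand_len[1L] / 2) {
        pts <- do.call(rbind, layer_pts[li2:nlay])
        proj <- as.vector(sweep(pts, 2, cyl$start) %*% cyl$axis)
        cyl$length <- max(cyl$length, max(proj))
        li2 <- nlay + 1L
      }
    }
    out[[length(out) + 1L]] <- list(start = cyl$start, axis = cyl$axis,
                                    length = cyl$length, radius = cyl$radius,
                                    coverage = best$coverage)
    prev_end <- cyl$start + cyl$axis * cyl$length
    prev_axis <- cyl$axis
    li <- li2
  }
  if (length(out) == 0L) return(.empty_cylinders())
  data.frame(
    start_x = vapply(out, function(c) c$start[1], 0),
    start_y = vapply(out, function(c) c$start[2], 0),
    start_z = vapply(out, function(c) c$start[3], 0),
    axis_x = vapply(out, function(c) c$axis[1], 0),
    axis_y = vapply(out, function(c) c$axis[2], 0),
    axis_z = vapply(out, function(c) c$axis[3], 0),
    length = vapply(out, function(c) c$length, 0),
    radius = vapply(out, function(c) c$radius, 0),
    coverage = vapply(out, function(c) c$coverage, 0))
}

.empty_cylinders <- function() {
  data.frame(start_x = numeric(0), start_y = numeric(0), start_z = numeric(0),
             axis_x = numeric(0), axis_y = numeric(0), axis_z = numeric(0),
             length = numeric(0), radius = numeric(0), coverage = numeric(0))
}

#' Reconstruction configuration
#'
#' Collects the tunable parameters of the reconstruction with the package
#' defaults.
#'
#' @param base_layers taproot expansion layers for root-base detection.
#' @param proximity root-base consolidation tolerance, as a fraction of the
#'   base-cylinder radius.
#' @param straightness minimum chord/path ratio kept by [merge_segments()].
#' @param stump_radius_factor stump cylinder radius as a multiple of the
#'   estimated taproot radius.
#' @param stump_depth_m depth band below the collar searched for the stump.
#' @param stump_radius_m optional explicit stump cylinder radius (overrides
#'   the estimate).
#' @param adjacency_factor patch adjacency threshold as a multiple of
#'   PatchDiam.
#' @param bridge_gap_factor occlusion-gap bridging limit as a multiple of
#'   PatchDiam (see [generate_cover()]); 0 disables bridging.
#' @param length_multipliers candidate cylinder lengths as multiples of
#'   PatchDiam.
#' @param n_azimuth azimuthal cells of the surface-coverage grid.
#' @param min_proximal_diam_cm coarse-root filter: minimum proximal diameter.
#' @param depth_threshold_m shallow/deep boundary.
#' @param lump_orders lump orders above 3 into 3.
#' @param include_taproot include the order-0 taproot chain in trait totals.
#' @return named list of class `qsm_config`.
#' @export
qsm_config <- function(base_layers = 3L, proximity = 0.5, straightness = 0.9,
                       stump_radius_factor = 1.5, stump_depth_m = 0.3,
                       stump_radius_m = NULL, adjacency_factor = 1.0,
                       bridge_gap_factor = 3.0,
                       length_multipliers = c(2, 3, 4, 6), n_azimuth = 8L,
                       min_proximal_diam_cm = 1.0, depth_threshold_m = 0.30,
                       lump_orders = TRUE, include_taproot = FALSE) {
  structure(list(base_layers = as.integer(base_layers), proximity = proximity,
                 straightness = straightness,
                 stump_radius_factor = stump_radius_factor,
                 stump_depth_m = stump_depth_m, stump_radius_m = stump_radius_m,
                 adjacency_factor = adjacency_factor,
                 bridge_gap_factor = bridge_gap_factor,
                 length_multipliers = length_multipliers,
                 n_azimuth = as.integer(n_azimuth),
                 min_proximal_diam_cm = min_proximal_diam_cm,
                 depth_threshold_m = depth_threshold_m,
                 lump_orders = lump_orders, include_taproot = include_taproot),
            class = "qsm_config")
}

#' Build a quantitative structure model
#'
#' Runs the full reconstruction chain: cover generation, stump detection,
#' root-base detection, segmentation, segment merging, cylinder modeling and
#' order assignment. Fully deterministic given `(cloud, patch_diam, seed,
#' config)`.
#'
#' @param cloud a [root_cloud()] with the frame set (collar at origin, Z up).
#' @param patch_diam PatchDiam, mm.
#' @param seed integer seed (cover randomization).
#' @param config a [qsm_config()].
#' @return object of class `root_qsm`: `cylinders` data.frame (id, parent,
#'   segment, order, start/axis/length/radius/coverage), `segments` summary,
#'   `provenance` (patch_diam, seed, config hash, patch count, unassigned
#'   patch count).
#' @export
build_qsm <- function(cloud, patch_diam, seed = 1L, config = qsm_config()) {
  stopifnot(inherits(cloud, "root_cloud"), inherits(config, "qsm_config"))
  cover <- generate_cover(cloud, patch_diam, seed = seed,
                          adjacency_factor = config$adjacency_factor,
                          bridge_gap_factor = config$bridge_gap_factor)
  stump <- find_stump(cover, cloud, radius_factor = config$stump_radius_factor,
                      depth = config$stump_depth_m,
                      radius = config$stump_radius_m)
  bases <- detect_root_bases(cover, stump, cloud,
                             layers = config$base_layers,
                             proximity = config$proximity)
  segs <- segment_roots(cover, bases, stump)
  segs <- merge_segments(segs, straightness = config$straightness)

  cyls <- list()
  seg_meta <- segs$segments
  for (i in seq_along(seg_meta)) {
    cdf <- model_segment(seg_meta[[i]], cloud, cover,
                         multipliers = config$length_multipliers,
                         n_azimuth = config$n_azimuth)
    if (nrow(cdf) == 0L) next
    cdf$segment <- seg_meta[[i]]$id
    cyls[[length(cyls) + 1L]] <- cdf
  }
  cylinders <- if (length(cyls)) do.call(rbind, cyls) else {
    e <- .empty_cylinders(); e$segment <- integer(0); e
  }
  qsm <- structure(list(
    cylinders = cylinders,
    segments = .segment_table(seg_meta),
    provenance = list(patch_diam = patch_diam, seed = as.integer(seed),
                      config_hash = .config_hash(unclass(config)),
                      n_patches = cover$n_patches,
                      n_unassigned = segs$n_unassigned)),
    class = "root_qsm")
  qsm <- .link_cylinders(qsm)
  qsm <- .enforce_taper(qsm)
  assign_orders(qsm, lump = config$lump_orders)
}

# Radius sanity constraint in the spirit of TreeQSM's taper correction:
# roots thin tipward, so a cylinder may not exceed 1.25x its within-segment
# predecessor; a segment's base cylinder (fitted on the junction point
# mixture, the usual outlier) may not exceed 1.25x its successor; and a
# child segment's first cylinder may not exceed its parent cylinder's
# radius. Applied parents-first over the cylinder tree.
.enforce_taper <- function(qsm, in_segment_slack = 1.25) {
  cyl <- qsm$cylinders
  if (nrow(cyl) < 2L) return(qsm)
  for (s in unique(cyl$segment)) {
    ids <- which(cyl$segment == s)
    if (length(ids) < 2L) next
    cap <- in_segment_slack * cyl$radius[ids[2L]]
    if (cyl$radius[ids[1L]] > cap) cyl$radius[ids[1L]] <- cap
  }
  qsm$cylinders <- cyl
  queue <- which(is.na(cyl$parent))
  while (length(queue)) {
    i <- queue[1L]
    queue <- queue[-1L]
    ch <- which(!is.na(cyl$parent) & cyl$parent == cyl$id[i])
    for (j in ch) {
      cap <- if (cyl$segment[j] == cyl$segment[i])
        in_segment_slack * cyl$radius[i] else cyl$radius[i]
      if (cyl$radius[j] > cap) cyl$radius[j] <- cap
      queue <- c(queue, j)
    }
  }
  qsm$cylinders <- cyl
  qsm
}

.segment_table <- function(seg_meta) {
  data.frame(
    id = vapply(seg_meta, function(s) s$id, 0L),
    parent = vapply(seg_meta, function(s) s$parent %||% NA_integer_, 0L),
    n_patches = vapply(seg_meta, function(s)
      sum(lengths(s$layers)), 0L),
    path_length = vapply(seg_meta, function(s) s$path_length, 0),
    chord = vapply(seg_meta, function(s) s$chord, 0))
}

# assign cylinder ids and parent links; snap each child segment's first start
# onto the nearest point of its parent's nearest cylinder axis
.link_cylinders <- function(qsm) {
  cyl <- qsm$cylinders
  if (nrow(cyl) == 0L) { qsm$cylinders <- cyl; return(qsm) }
  cyl$id <- seq_len(nrow(cyl))
  cyl$parent <- NA_integer_
  segs <- qsm$segments
  first_of_seg <- vapply(segs$id, function(s) cyl$id[cyl$segment == s][1],
                         0L)
  names(first_of_seg) <- as.character(segs$id)
  # within-segment chain links
  for (s in segs$id) {
    ids <- cyl$id[cyl$segment == s]
    if (length(ids) > 1L)
      cyl$parent[ids[-1]] <- ids[-length(ids)]
  }
  # cross-segment links
  for (k in seq_len(nrow(segs))) {
    if (is.na(segs$parent[k])) next
    child_first <- first_of_seg[[as.character(segs$id[k])]]
    if (is.na(child_first)) next
    pids <- cyl$id[cyl$segment == segs$parent[k]]
    if (length(pids) == 0L) next
    p0 <- as.numeric(cyl[child_first, c("start_x", "start_y", "start_z")])
    # nearest parent cylinder (by distance from child start to axis segment)
    best <- pids[1L]; bestd <- Inf; bestfoot <- p0
    for (pid in pids) {
      a <- as.numeric(cyl[pid, c("start_x", "start_y", "start_z")])
      w <- as.numeric(cyl[pid, c("axis_x", "axis_y", "axis_z")])
      t <- min(max(sum((p0 - a) * w), 0), cyl$length[pid])
      foot <- a + t * w
      d <- sqrt(sum((p0 - foot)^2))
      if (d < bestd) { bestd <- d; best <- pid; bestfoot <- foot }
    }
    cyl$parent[child_first] <- best
    # extend the child's base cylinder back to the parent's surface,
    # keeping its end fixed (the junction gap is real root length)
    end0 <- p0 + as.numeric(cyl[child_first, c("axis_x", "axis_y",
                                               "axis_z")]) *
      cyl$length[child_first]
    u <- end0 - bestfoot
    nu <- sqrt(sum(u^2))
    if (nu > 1e-9 && nu > cyl$radius[best]) {
      u <- u / nu
      newstart <- bestfoot + u * cyl$radius[best]
      cyl[child_first, c("start_x", "start_y", "start_z")] <- newstart
      cyl[child_first, c("axis_x", "axis_y", "axis_z")] <- u
      cyl$length[child_first] <- sqrt(sum((end0 - newstart)^2))
    }
  }
  qsm$cylinders <- cyl
  qsm
}

#' @export
print.root_qsm <- function(x, ...) {
  cat(sprintf(
    "<root_qsm> %d cylinders in %d segments (PatchDiam %.1f mm, seed %d)\n",
    nrow(x$cylinders), nrow(x$segments), x$provenance$patch_diam,
    x$provenance$seed))
  cat(sprintf("  total volume %.3f dm^3, total length %.2f m\n",
              qsm_volume(x) * 1000, sum(x$cylinders$length)))
  invisible(x)
}

#' Total QSM volume (m^3)
#'
#' `sum(pi * radius^2 * length)` over all cylinders.
#' @param qsm a [build_qsm()] result.
#' @export
qsm_volume <- function(qsm) {
  sum(pi * qsm$cylinders$radius^2 * qsm$cylinders$length)
}

#' Export a QSM as tabular text
#'
#' One cylinder per row: id, parent, segment, order, start xyz (m), axis xyz,
#' length_m, radius_m, coverage. Tab-separated with a header.
#'
#' @param qsm a [build_qsm()] result.
#' @param path output file.
#' @export
export_qsm <- function(qsm, path) {
  cyl <- qsm$cylinders
  out <- data.frame(id = cyl$id, parent = cyl$parent, segment = cyl$segment,
                    order = cyl$order,
                    start_x = cyl$start_x, start_y = cyl$start_y,
                    start_z = cyl$start_z, axis_x = cyl$axis_x,
                    axis_y = cyl$axis_y, axis_z = cyl$axis_z,
                    length_m = cyl$length, radius_m = cyl$radius,
                    coverage = cyl$coverage)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a QSM as an OBJ mesh for visualization
#'
#' Each cylinder becomes an open prism with `sides` rectangular facets.
#'
#' @param qsm a [build_qsm()] result.
#' @param path output `.obj` file.
#' @param sides polygon sides per cylinder.
#' @export
export_qsm_obj <- function(qsm, path, sides = 12L) {
  cyl <- qsm$cylinders
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# rootqsm cylinder mesh", con)
  voff <- 0L
  for (i in seq_len(nrow(cyl))) {
    a <- as.numeric(cyl[i, c("start_x", "start_y", "start_z")])
    w <- as.numeric(cyl[i, c("axis_x", "axis_y", "axis_z")])
    b <- .perp_basis(w)
    ang <- 2 * pi * (seq_len(sides) - 1) / sides
    ring0 <- t(a + cyl$radius[i] * (outer(b$u, cos(ang)) + outer(b$v, sin(ang))))
    ring1 <- sweep(ring0, 2, w * cyl$length[i], "+")
    verts <- rbind(ring0, ring1)
    writeLines(sprintf("v %.6f %.6f %.6f", verts[, 1], verts[, 2], verts[, 3]),
               con)
    j <- seq_len(sides)
    jn <- c(2:sides, 1L)
    writeLines(sprintf("f %d %d %d %d", voff + j, voff + jn,
                       voff + sides + jn, voff + sides + j), con)
    voff <- voff + 2L * sides
  }
  invisible(path)
}
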