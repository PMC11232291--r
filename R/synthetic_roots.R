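#' Specification of a procedural root system
#'
#' Parameterized to emulate excavated mature-conifer coarse-root systems:
#' roughly 1 to 1.5 m deep, extending about 1.5 m horizontally, with a
#' vertical taproot, mostly shallow lateral first-order roots, and smaller
#' second/third-order branches. Azimuthal asymmetry weights emulate the
#' downslope/windward bias of root allocation.
#'
#' @param taproot_depth taproot length, m.
#' @param taproot_radius taproot basal radius, m.
#' @param n_first number of first-order roots.
#' @param first_radius range of first-order proximal radii, m.
#' @param first_length range of first-order root lengths, m.
#' @param second_per_first expected second-order branches per first-order
#'   root (Poisson).
#' @param third_per_second expected third-order branches per second-order
#'   root (Poisson).
#' @param branch_angle mean and sd (degrees) of the branching angle from the
#'   parent axis for orders >= 2.
#' @param dive_angle mean and sd (degrees) of the first-order downward tilt
#'   from horizontal.
#' @param taper fraction of the proximal radius lost by the tip (0 = no
#'   taper).
#' @param asymmetry azimuthal weights for quadrants N, E, S, W (sum to 1).
#' @param curvature axis wander, radians per meter of root.
#' @param step polyline step, m.
#' @param seed random seed.
#' @return list of class `root_system_spec`.
#' @export
root_system_spec <- function(taproot_depth = 1.2, taproot_radius = 0.07,
                             n_first = 10L, first_radius = c(0.018, 0.032),
                             first_length = c(0.7, 1.1),
                             second_per_first = 0.8, third_per_second = 0.5,
                             branch_angle = c(50, 10),
                             dive_angle = c(15, 8), taper = 0.6,
                             asymmetry = c(N = 0.35, E = 0.15, S = 0.15,
                                           W = 0.35),
                             curvature = 0.35, step = 0.05, seed = 1L) {
  .assert_scalar_pos(taproot_depth, "taproot_depth")
  .assert_scalar_pos(taproot_radius, "taproot_radius")
  if (abs(sum(asymmetry) - 1) > 1e-9)
    stop("asymmetry weights must sum to 1", call. = FALSE)
  if (any(first_radius <= 0) || any(first_length <= 0))
    stop("radii and lengths must be positive", call. = FALSE)
  if (taper < 0 || taper >= 1) stop("taper must be in [0, 1)", call. = FALSE)
  structure(list(taproot_depth = taproot_depth,
                 taproot_radius = taproot_radius,
                 n_first = as.integer(n_first), first_radius = first_radius,
                 first_length = first_length,
                 second_per_first = second_per_first,
                 third_per_second = third_per_second,
                 branch_angle = branch_angle, dive_angle = dive_angle,
                 taper = taper, asymmetry = asymmetry, curvature = curvature,
                 step = step, seed = as.integer(seed)),
            class = "root_system_spec")
}

# grow one root as a polyline: start point, initial direction, length,
# proximal/tip radius; curvature applied as a per-step random axis wobble
.grow_polyline <- function(start, dir, length, r0, r1, step, curvature) {
  nsteps <- max(2L, ceiling(length / step))
  h <- length / nsteps
  pts <- matrix(0, nsteps + 1L, 3)
  pts[1L, ] <- start
  d <- .unit(dir)
  for (i in seq_len(nsteps)) {
    pts[i + 1L, ] <- pts[i, ] + d * h
    if (curvature > 0) {
      b <- .perp_basis(d)
      ang <- stats::rnorm(2, 0, curvature * h)
      d <- .unit(d + ang[1] * b$u + ang[2] * b$v)
    }
  }
  radii <- r0 + (r1 - r0) * seq(0, 1, length.out = nsteps + 1L)
  list(points = pts, radii = radii)
}

# arc-length positions of polyline vertices
.arc_pos <- function(pts) {
  c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
}

# interpolate position/radius/direction at arc position s
.at_arc <- function(poly, s) {
  pos <- .arc_pos(poly$points)
  s <- min(max(s, 0), pos[length(pos)])
  i <- max(1L, findInterval(s, pos, rightmost.closed = TRUE))
  i <- min(i, nrow(poly$points) - 1L)
  f <- (s - pos[i]) / max(pos[i + 1L] - pos[i], 1e-12)
  list(point = poly$points[i, ] + f * (poly$points[i + 1L, ] - poly$points[i, ]),
       radius = poly$radii[i] + f * (poly$radii[i + 1L] - poly$radii[i]),
       dir = .unit(poly$points[i + 1L, ] - poly$points[i, ]))
}

#' Generate a procedural root system with known traits
#'
#' Recursive construction: the taproot is a tapered near-vertical polyline
#' from the collar; first-order roots attach to it at sampled depths with
#' azimuths drawn from the quadrant asymmetry weights; higher orders attach
#' to their parents at sampled arc positions. Branches whose radius would
#' fall below 0.1 mm are truncated. Deterministic given the seed carried by
#' the system specification.
#'
#' @param spec a [root_system_spec()].
#' @return object of class `truth_system`: `roots` (data.frame: root_id,
#'   parent_root, order), `polylines` (per root: vertex matrix + radii),
#'   `cylinders` (generative cylinder table with per-cylinder order labels),
#'   and the `spec`.
#' @export
generate_system <- function(spec) {
  stopifnot(inherits(spec, "root_system_spec"))
  set.seed(spec$seed)
  # quadrant centre azimuths, degrees from north (+X) toward east (-Y)
  quads <- c(N = 0, E = 90, S = 180, W = 270)
  polylines <- list()
  roots <- list()
  # taproot: near-vertical, mild wander, tapering to 25% basal radius
  tap <- .grow_polyline(c(0, 0, 0), c(0, 0, -1), spec$taproot_depth,
                        spec$taproot_radius, 0.25 * spec$taproot_radius,
                        spec$step, spec$curvature / 2)
  polylines[[1L]] <- tap
  roots[[1L]] <- data.frame(root_id = 1L, parent_root = NA_integer_,
                            order = 0L)
  tap_id <- 1L

  for (k in seq_len(spec$n_first)) {
    # quadrant by asymmetry weights, uniform azimuth within the quadrant
    q <- sample(names(spec$asymmetry), 1L, prob = spec$asymmetry)
    az <- (quads[[q]] + stats::runif(1, -45, 45)) * pi / 180
    depth <- stats::runif(1, 0.05, 0.35)
    att <- .at_arc(tap, depth)
    dive <- pmin(pmax(stats::rnorm(1, spec$dive_angle[1],
                                   spec$dive_angle[2]), 0), 60) * pi / 180
    # frame: X = north, Y = west; east = -Y
    dir <- c(cos(az) * cos(dive), -sin(az) * cos(dive), -sin(dive))
    r0 <- stats::runif(1, spec$first_radius[1], spec$first_radius[2])
    len <- stats::runif(1, spec$first_length[1], spec$first_length[2])
    start <- att$point + .unit(c(dir[1], dir[2], 0)) * att$radius
    poly <- .grow_polyline(start, dir, len, r0, (1 - spec$taper) * r0,
                           spec$step, spec$curvature)
    rid <- length(polylines) + 1L
    polylines[[rid]] <- poly
    roots[[rid]] <- data.frame(root_id = rid, parent_root = tap_id,
                               order = 1L)
    # second order
    n2 <- stats::rpois(1, spec$second_per_first)
    for (j in seq_len(n2)) {
      u <- stats::runif(1, 0.2, 0.7)
      pos <- .arc_pos(poly$points)
      att2 <- .at_arc(poly, u * pos[length(pos)])
      r2 <- att2$radius * stats::runif(1, 0.45, 0.65)
      if (r2 < 1e-4) next
      len2 <- len * stats::runif(1, 0.4, 0.7)
      bang <- stats::rnorm(1, spec$branch_angle[1], spec$branch_angle[2]) *
        pi / 180
      roll <- stats::runif(1, 0, 2 * pi)
      b <- .perp_basis(att2$dir)
      lat <- cos(roll) * b$u + sin(roll) * b$v
      dir2 <- .unit(cos(bang) * att2$dir + sin(bang) * lat)
      poly2 <- .grow_polyline(att2$point + lat * att2$radius, dir2, len2,
                              r2, (1 - spec$taper) * r2, spec$step,
                              spec$curvature)
      rid2 <- length(polylines) + 1L
      polylines[[rid2]] <- poly2
      roots[[rid2]] <- data.frame(root_id = rid2, parent_root = rid,
                                  order = 2L)
      # third order
      n3 <- stats::rpois(1, spec$third_per_second)
      for (m in seq_len(n3)) {
        u3 <- stats::runif(1, 0.2, 0.7)
        pos2 <- .arc_pos(poly2$points)
        att3 <- .at_arc(poly2, u3 * pos2[length(pos2)])
        r3 <- att3$radius * stats::runif(1, 0.45, 0.65)
        if (r3 < 1e-4) next
        len3 <- len2 * stats::runif(1, 0.4, 0.7)
        bang3 <- stats::rnorm(1, spec$branch_angle[1],
                              spec$branch_angle[2]) * pi / 180
        roll3 <- stats::runif(1, 0, 2 * pi)
        b3 <- .perp_basis(att3$dir)
        lat3 <- cos(roll3) * b3$u + sin(roll3) * b3$v
        dir3 <- .unit(cos(bang3) * att3$dir + sin(bang3) * lat3)
        poly3 <- .grow_polyline(att3$point + lat3 * att3$radius, dir3, len3,
                                r3, (1 - spec$taper) * r3, spec$step,
                                spec$curvature)
        rid3 <- length(polylines) + 1L
        polylines[[rid3]] <- poly3
        roots[[rid3]] <- data.frame(root_id = rid3, parent_root = rid2,
                                    order = 3L)
      }
    }
  }
  roots <- do.call(rbind, roots)
  cylinders <- .truth_cylinders(polylines, roots)
  structure(list(roots = roots, polylines = polylines,
                 cylinders = cylinders, spec = spec),
            class = "truth_system")
}

# generative cylinders: one per polyline edge, radius at the edge midpoint
.truth_cylinders <- function(polylines, roots) {
  out <- list()
  for (i in seq_len(nrow(roots))) {
    poly <- polylines[[roots$root_id[i]]]
    p <- poly$points
    n <- nrow(p) - 1L
    r <- (poly$radii[-1] + poly$radii[-(n + 1L)]) / 2
    d <- diff(p)
    len <- sqrt(rowSums(d^2))
    out[[i]] <- data.frame(
      root_id = roots$root_id[i], order = roots$order[i],
      start_x = p[-(n + 1L), 1], start_y = p[-(n + 1L), 2],
      start_z = p[-(n + 1L), 3],
      axis_x = d[, 1] / len, axis_y = d[, 2] / len, axis_z = d[, 3] / len,
      length = len, radius = r)
  }
  cyl <- do.call(rbind, out)
  cyl$cyl_id <- seq_len(nrow(cyl))
  cyl
}

#' @export
print.truth_system <- function(x, ...) {
  cat(sprintf("<truth_system> %d roots (%s), %d generative cylinders\n",
              nrow(x$roots),
              paste(sprintf("order %d: %d", 0:3,
                            tabulate(x$roots$order + 1L, 4L)),
                    collapse = ", "),
              nrow(x$cylinders)))
  invisible(x)
}

#' Analytic ground-truth traits of a generated system
#'
#' Sums length and volume over the generative cylinders with the same
#' stratification and filter rules as [compute_traits()]: quadrant/depth by
#' cylinder midpoint, root count by the root's base cylinder, proximal
#' diameter from the root's first vertex radius, coarse filter at
#' `min_proximal_diam`.
#'
#' @param truth a [generate_system()] result.
#' @inheritParams compute_traits
#' @return a `root_traits` object.
#' @export
truth_traits <- function(truth, min_proximal_diam = 1.0,
                         depth_threshold = 0.30, include_taproot = FALSE) {
  stopifnot(inherits(truth, "truth_system"))
  cyl <- truth$cylinders
  midx <- cyl$start_x + cyl$axis_x * cyl$length / 2
  midy <- cyl$start_y + cyl$axis_y * cyl$length / 2
  midz <- cyl$start_z + cyl$axis_z * cyl$length / 2
  df <- data.frame(
    root = cyl$root_id, order = cyl$order, length = cyl$length,
    volume = pi * cyl$radius^2 * cyl$length * 1000,
    quadrant = quadrant_of(midx, midy),
    depth = factor(ifelse(-midz < depth_threshold, "shallow", "deep"),
                   levels = c("shallow", "deep")))
  base <- !duplicated(cyl$root_id)
  pr <- data.frame(
    root = cyl$root_id[base], order = cyl$order[base],
    proximal_diam_cm = 200 * vapply(truth$polylines[cyl$root_id[base]],
                                    function(p) p$radii[1], 0),
    quadrant = df$quadrant[base], depth = df$depth[base])
  pr$length <- as.vector(tapply(df$length, df$root, sum)[
    as.character(pr$root)])
  pr$volume <- as.vector(tapply(df$volume, df$root, sum)[
    as.character(pr$root)])
  .aggregate_traits(df, pr, min_proximal_diam, depth_threshold,
                    include_taproot)
}

#' Scanner configuration
#'
#' Emulates a tripod terrestrial laser scanner: by default three viewpoints
#' at 120-degree spacing, 4.5 m range (within the 3-6 m working range),
#' 2 mm Gaussian range noise and a 4 mm spot size. The spot size is recorded
#' metadata; beam-footprint mixing is not simulated.
#'
#' @param n_viewpoints number of scan positions.
#' @param azimuths viewpoint azimuths, degrees (default even spacing).
#' @param range_m horizontal distance of the scanner from the collar axis.
#' @param height_m scanner height relative to the collar plane.
#' @param range_noise_mm Gaussian range noise sd, mm.
#' @param spot_size_mm beam spot size, mm (metadata only).
#' @param angular_step_deg angular sampling step, degrees.
#' @param occlusion keep only the nearest intersection per ray.
#' @param seed seed for the range noise.
#' @return list of class `scanner_spec`.
#' @export
scanner_spec <- function(n_viewpoints = 3L, azimuths = NULL, range_m = 4.5,
                         height_m = -0.5, range_noise_mm = 2,
                         spot_size_mm = 4, angular_step_deg = 0.05,
                         occlusion = TRUE, seed = 1L) {
  if (n_viewpoints < 1L) stop("need at least one viewpoint", call. = FALSE)
  if (range_noise_mm < 0) stop("range noise must be >= 0", call. = FALSE)
  if (is.null(azimuths))
    azimuths <- (seq_len(n_viewpoints) - 1L) * 360 / n_viewpoints
  structure(list(n_viewpoints = as.integer(n_viewpoints),
                 azimuths = azimuths, range_m = range_m, height_m = height_m,
                 range_noise_mm = range_noise_mm,
                 spot_size_mm = spot_size_mm,
                 angular_step_deg = angular_step_deg,
                 occlusion = isTRUE(occlusion), seed = as.integer(seed)),
            class = "scanner_spec")
}

#' Simulate a terrestrial laser scan of a generated root system
#'
#' For each viewpoint, rays on a regular angular grid are intersected with
#' the generative cylinders; with occlusion only the nearest intersection
#' survives. Gaussian range noise is added along each ray. The union over
#' viewpoints is returned with per-point truth labels.
#'
#' @param truth a [generate_system()] result.
#' @param scanner a [scanner_spec()].
#' @return a [root_cloud()] with attribute-style element `labels`
#'   (data.frame: `cyl_id`, `root_id`, `order` per point).
#' @export
scan_system <- function(truth, scanner = scanner_spec()) {
  stopifnot(inherits(truth, "truth_system"), inherits(scanner, "scanner_spec"))
  cyl <- truth$cylinders
  cstart <- as.matrix(cyl[, c("start_x", "start_y", "start_z")])
  caxis <- as.matrix(cyl[, c("axis_x", "axis_y", "axis_z")])
  ends <- cstart + caxis * cyl$length
  lo <- pmin(apply(cstart, 2, min), apply(ends, 2, min)) - max(cyl$radius)
  hi <- pmax(apply(cstart, 2, max), apply(ends, 2, max)) + max(cyl$radius)
  corners <- as.matrix(expand.grid(c(lo[1], hi[1]), c(lo[2], hi[2]),
                                   c(lo[3], hi[3])))
  set.seed(scanner$seed)
  step <- scanner$angular_step_deg * pi / 180
  allpts <- list(); alllab <- list()
  for (azdeg in scanner$azimuths) {
    az <- azdeg * pi / 180
    origin <- c(cos(az) * scanner$range_m, -sin(az) * scanner$range_m,
                scanner$height_m)
    # angular extent of the bounding box seen from this viewpoint
    rel <- sweep(corners, 2, origin)
    azc <- atan2(rel[, 2], rel[, 1])
    # unwrap around the central direction to avoid branch cuts
    az0 <- atan2(mean(rel[, 2]), mean(rel[, 1]))
    azc <- (azc - az0 + pi) %% (2 * pi) - pi
    elc <- atan2(rel[, 3], sqrt(rel[, 1]^2 + rel[, 2]^2))
    azr <- range(azc) + c(-2, 2) * step
    elr <- range(elc) + c(-2, 2) * step
    azs <- seq(azr[1], azr[2], by = step) + az0
    els <- seq(elr[1], elr[2], by = step)
    dirs <- cbind(
      rep(cos(azs), times = length(els)) * rep(cos(els), each = length(azs)),
      rep(sin(azs), times = length(els)) * rep(cos(els), each = length(azs)),
      rep(sin(els), each = length(azs)))
    res <- cpp_scan_rays(origin, dirs, cstart, caxis, cyl$length, cyl$radius,
                         scanner$range_noise_mm / 1000, scanner$occlusion)
    if (nrow(res$points) > 0L) {
      allpts[[length(allpts) + 1L]] <- res$points
      alllab[[length(alllab) + 1L]] <- res$cyl_id
    }
  }
  if (length(allpts) == 0L)
    stop("no ray intersections; empty simulated cloud", call. = FALSE)
  pts <- do.call(rbind, allpts)
  ids <- unlist(alllab, use.names = FALSE)
  cloud <- root_cloud(pts)
  cloud$labels <- data.frame(cyl_id = cyl$cyl_id[ids],
                             root_id = cyl$root_id[ids],
                             order = cyl$order[ids])
  cloud
}

#' Emulate contact digitization of a generated system
#'
#' Resamples each root polyline at fixed arc-length steps (including both
#' ends) with the true local diameters: `curved_step` on curved roots,
#' `straight_step` where the polyline is collinear, mirroring field
#' digitizing practice of measuring densely where roots curve.
#'
#' @param truth a [generate_system()] result.
#' @param curved_step,straight_step sampling steps, m.
#' @return a [reference_record()].
#' @export
digitize_system <- function(truth, curved_step = 0.02,
                            straight_step = 0.15) {
  stopifnot(inherits(truth, "truth_system"))
  rows <- list()
  for (i in seq_len(nrow(truth$roots))) {
    rid <- truth$roots$root_id[i]
    poly <- truth$polylines[[rid]]
    pos <- .arc_pos(poly$points)
    arc <- pos[length(pos)]
    # collinearity: max deviation of vertices from the chord
    chord <- poly$points[nrow(poly$points), ] - poly$points[1L, ]
    u <- .unit(chord)
    rel <- sweep(poly$points, 2, poly$points[1L, ])
    dev <- sqrt(pmax(rowSums(rel^2) - as.vector(rel %*% u)^2, 0))
    step <- if (max(dev) < 1e-6) straight_step else curved_step
    nseg <- max(1L, ceiling(arc / step - 1e-9))
    ss <- seq(0, arc, length.out = nseg + 1L)
    at <- lapply(ss, function(s) .at_arc(poly, s))
    rows[[length(rows) + 1L]] <- data.frame(
      root_id = rid,
      parent_id = truth$roots$parent_root[i] %||% NA_integer_,
      order = truth$roots$order[i],
      seq = seq_along(ss),
      x = vapply(at, function(a) a$point[1], 0),
      y = vapply(at, function(a) a$point[2], 0),
      z = vapply(at, function(a) a$point[3], 0),
      d1 = vapply(at, function(a) 200 * a$radius, 0),
      d2 = NA_real_, d2_azimuth = NA_real_)
  }
  reference_record(do.call(rbind, rows))
}
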