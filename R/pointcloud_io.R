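#' Point cloud container
#'
#' A point cloud in the root coordinate frame: X = geographic north,
#' Y = west (right-handed), Z = up, origin at the root collar, units meters.
#'
#' @param points numeric N x 3 matrix of coordinates (m).
#' @param frame label recording the orientation convention.
#' @param intensity optional per-point intensity.
#' @return object of class `root_cloud`.
#' @export
root_cloud <- function(points, frame = "collar/north-X/up-Z",
                       intensity = NULL) {
  points <- as.matrix(points)
  if (!is.numeric(points) || ncol(points) != 3L)
    stop("`points` must be a numeric N x 3 matrix", call. = FALSE)
  if (nrow(points) < 1L) stop("empty point cloud", call. = FALSE)
  if (!all(is.finite(points))) stop("non-finite coordinates", call. = FALSE)
  dimnames(points) <- list(NULL, c("x", "y", "z"))
  if (!is.null(intensity) && length(intensity) != nrow(points))
    stop("intensity length must match point count", call. = FALSE)
  structure(list(points = points, frame = frame, intensity = intensity),
            class = "root_cloud")
}

#' @export
print.root_cloud <- function(x, ...) {
  cat(sprintf("<root_cloud> %d points, frame: %s\n", nrow(x$points), x$frame))
  rng <- apply(x$points, 2, range)
  cat(sprintf("  extent (m): x [%.3f, %.3f]  y [%.3f, %.3f]  z [%.3f, %.3f]\n",
              rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  invisible(x)
}

#' Read a point cloud from LAS or XYZ text
#'
#' LAS 1.2+ point formats 0-3 are supported; coordinates are converted to
#' meters using the header scale/offset. XYZ is whitespace-delimited text,
#' one point per line, meters.
#'
#' @param path input file.
#' @param format `"las"`, `"xyz"` or `"auto"` (by file extension, falling
#'   back to content sniffing).
#' @return a [root_cloud()].
#' @export
read_cloud <- function(path, format = c("auto", "las", "xyz")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop(sprintf("file '%s' does not exist", path), call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "las") "las"
      else if (ext %in% c("xyz", "txt", "pts")) "xyz"
      else {
        sig <- readBin(path, "raw", n = 4)
        if (identical(rawToChar(sig), "LASF")) "las" else "xyz"
      }
  }
  if (format == "las") {
    las <- .las_read(path)
    root_cloud(las$points, intensity = las$intensity)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) stop("empty point cloud file", call. = FALSE)
    fields <- strsplit(trimws(lines), "[[:space:]]+")
    nf <- lengths(fields)
    if (any(nf < 3L))
      stop(sprintf("malformed XYZ line %d: '%s'", which(nf < 3L)[1],
                   lines[which(nf < 3L)[1]]), call. = FALSE)
    xyz <- vapply(fields, function(f) as.numeric(f[1:3]), numeric(3))
    bad <- which(colSums(!is.finite(xyz)) > 0L)
    if (length(bad))
      stop(sprintf("malformed XYZ line %d: '%s'", bad[1], lines[bad[1]]),
           call. = FALSE)
    root_cloud(t(xyz))
  }
}

#' Write a point cloud to LAS or XYZ text
#'
#' LAS output uses version 1.2, point format 0, scale 0.001 m, so round-trip
#' coordinates agree within 0.0005 m per axis.
#'
#' @param cloud a [root_cloud()].
#' @param path output file.
#' @param format `"las"` or `"xyz"`.
#' @export
write_cloud <- function(cloud, path, format = c("las", "xyz")) {
  format <- match.arg(format)
  stopifnot(inherits(cloud, "root_cloud"))
  if (nrow(cloud$points) < 1L) stop("empty point cloud", call. = FALSE)
  if (format == "las") {
    .las_write(cloud$points, path, intensity = cloud$intensity)
  } else {
    utils::write.table(format(cloud$points, digits = 12, trim = TRUE,
                              scientific = FALSE),
                       path, row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}

#' Establish the root coordinate frame
#'
#' Applies the rigid transform placing the collar at the origin with north
#' along +X and up along +Z (Y = west completes a right-handed frame). With
#' `invert` the cloud is first flipped about the horizontal plane through the
#' collar, undoing the upside-down posture of a root system scanned resting
#' on its cut stump face.
#'
#' @param cloud a [root_cloud()].
#' @param collar 3D position of the root collar in the input coordinates.
#' @param north,up non-parallel direction vectors of geographic north and up
#'   in the input coordinates.
#' @param invert flip about the horizontal plane first.
#' @return transformed [root_cloud()].
#' @export
set_frame <- function(cloud, collar = c(0, 0, 0), north = c(1, 0, 0),
                      up = c(0, 0, 1), invert = FALSE) {
  stopifnot(inherits(cloud, "root_cloud"))
  z <- .unit(up)
  nproj <- north - sum(north * z) * z
  if (sqrt(sum(nproj^2)) < 1e-9)
    stop("`north` and `up` directions are parallel", call. = FALSE)
  x <- .unit(nproj)
  y <- .cross3(z, x)                       # y = z x x so that x cross y = z
  p <- cloud$points
  if (invert) p[, 3] <- 2 * collar[3] - p[, 3]
  p <- sweep(p, 2, as.numeric(collar))
  rot <- rbind(x, y, z)
  root_cloud(p %*% t(rot), frame = "collar/north-X/up-Z",
             intensity = cloud$intensity)
}

#' Estimate point density and spacing
#'
#' Covers the cloud with patches of the probe diameter, projects each patch
#' onto its two largest principal components, takes the convex-hull area, and
#' reports density = points / area (points per mm^2). The median point
#' spacing is the median over patches of `1 / sqrt(density)`. Patches with
#' fewer than 3 points or a degenerate (near-collinear) hull are skipped and
#' counted in `n_skipped`.
#'
#' @param cloud a [root_cloud()] with at least 3 points.
#' @param probe_patch_diam probe patch diameter, mm.
#' @param seed seed for the randomized covering.
#' @return list with `density` (points/mm^2 per retained patch), `area_mm2`,
#'   `median_spacing_mm`, `n_patches`, `n_skipped`.
#' @export
estimate_density <- function(cloud, probe_patch_diam = 30, seed = 1L) {
  stopifnot(inherits(cloud, "root_cloud"))
  .assert_scalar_pos(probe_patch_diam, "probe_patch_diam")
  if (nrow(cloud$points) < 3L)
    stop("density estimation needs at least 3 points", call. = FALSE)
  cov <- generate_cover(cloud, patch_diam = probe_patch_diam, seed = seed)
  dens <- area <- numeric(0)
  skipped <- 0L
  for (idx in cov$patches) {
    if (length(idx) < 3L) { skipped <- skipped + 1L; next }
    p <- cloud$points[idx, , drop = FALSE] * 1000      # mm
    p <- sweep(p, 2, colMeans(p))
    sv <- svd(p, nu = 0, nv = 2)
    xy <- p %*% sv$v
    h <- grDevices::chull(xy)
    if (length(h) < 3L) { skipped <- skipped + 1L; next }
    a <- .polygon_area(xy[h, , drop = FALSE])
    if (a < 1e-9) { skipped <- skipped + 1L; next }
    dens <- c(dens, length(idx) / a)
    area <- c(area, a)
  }
  if (length(dens) == 0L)
    stop("all patches degenerate; cannot estimate density", call. = FALSE)
  list(density = dens, area_mm2 = area,
       median_spacing_mm = stats::median(1 / sqrt(dens)),
       n_patches = cov$n_patches, n_skipped = skipped)
}

#' Radius outlier filter (convenience, off by default in the pipeline)
#'
#' Removes points with fewer than `min_neighbors` other points within
#' `radius`. Background and noise removal is normally done upstream; this is
#' a light convenience filter for isolated stragglers.
#'
#' @param cloud a [root_cloud()].
#' @param radius neighbourhood radius, m.
#' @param min_neighbors minimum neighbour count to keep a point.
#' @return filtered [root_cloud()].
#' @export
filter_outliers <- function(cloud, radius = 0.01, min_neighbors = 3L) {
  stopifnot(inherits(cloud, "root_cloud"))
  n <- nrow(cloud$points)
  keep <- rep(TRUE, n)
  d2 <- radius^2
  # exact pairwise count for small clouds, sweep along x otherwise
  if (n <= 5000L) {
    dm <- as.matrix(stats::dist(cloud$points))
    keep <- rowSums(dm <= radius) - 1L >= min_neighbors
  } else {
    ord <- order(cloud$points[, 1])
    x <- cloud$points[ord, 1]
    cnt <- integer(n)
    lo <- 1L
    for (i in seq_len(n)) {
      while (x[i] - x[lo] > radius) lo <- lo + 1L
      hi <- i
      while (hi < n && x[hi + 1L] - x[i] <= radius) hi <- hi + 1L
      js <- lo:hi
      dd <- colSums((t(cloud$points[ord[js], , drop = FALSE]) -
                       cloud$points[ord[i], ])^2)
      cnt[ord[i]] <- sum(dd <= d2) - 1L
    }
    keep <- cnt >= min_neighbors
  }
  if (!any(keep)) stop("filter removed all points", call. = FALSE)
  root_cloud(cloud$points[keep, , drop = FALSE], frame = cloud$frame,
             intensity = cloud$intensity[keep])
}
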