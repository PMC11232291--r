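# Digitized reference records: a flat, documented dialect carrying the same
# information as a plant-architecture MTG (topology code + coordinates +
# diameters per measurement point), read/written as TSV.

.ref_columns <- c("root_id", "parent_id", "order", "seq", "x", "y", "z",
                  "d1", "d2", "d2_azimuth")

#' Construct a reference record
#'
#' @param points data.frame with columns `root_id`, `parent_id` (0 or NA for
#'   the topmost axis), `order`, `seq` (measurement-point index along the
#'   root), `x`, `y`, `z` (m), `d1` (largest diameter, cm), optional `d2`
#'   (perpendicular diameter, cm) and `d2_azimuth` (degrees).
#' @return object of class `reference_record`.
#' @export
reference_record <- function(points) {
  points <- as.data.frame(points)
  missing_cols <- setdiff(c("root_id", "parent_id", "order", "seq",
                            "x", "y", "z", "d1"), names(points))
  if (length(missing_cols))
    stop(sprintf("reference record is missing columns: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  if (is.null(points$d2)) points$d2 <- NA_real_
  if (is.null(points$d2_azimuth)) points$d2_azimuth <- NA_real_
  points <- points[order(points$root_id, points$seq), .ref_columns]
  rownames(points) <- NULL
  bad <- which(!is.finite(points$d1) | points$d1 <= 0)
  if (length(bad))
    stop(sprintf("row %d: diameter d1 must be positive", bad[1]),
         call. = FALSE)
  bad2 <- which(!is.na(points$d2) & points$d2 <= 0)
  if (length(bad2))
    stop(sprintf("row %d: diameter d2 must be positive", bad2[1]),
         call. = FALSE)
  # topology validation
  roots <- unique(points[, c("root_id", "parent_id", "order")])
  if (anyDuplicated(roots$root_id))
    stop("inconsistent parent_id/order within a root", call. = FALSE)
  cnt <- table(points$root_id)
  if (any(cnt < 2L))
    stop(sprintf("root %s has fewer than 2 measurement points",
                 names(cnt)[cnt < 2L][1]), call. = FALSE)
  ids <- roots$root_id
  for (i in seq_len(nrow(roots))) {
    p <- roots$parent_id[i]
    if (!is.na(p) && p != 0 && !(p %in% ids))
      stop(sprintf("root %d: orphan parent id %d", roots$root_id[i], p),
           call. = FALSE)
  }
  # cycle check by walking parents
  for (i in seq_len(nrow(roots))) {
    seen <- integer(0)
    j <- roots$root_id[i]
    while (TRUE) {
      if (j %in% seen)
        stop(sprintf("cycle in topology at root %d", j), call. = FALSE)
      seen <- c(seen, j)
      p <- roots$parent_id[match(j, roots$root_id)]
      if (is.na(p) || p == 0) break
      j <- p
    }
  }
  structure(list(points = points, roots = roots), class = "reference_record")
}

#' @export
print.reference_record <- function(x, ...) {
  cat(sprintf("<reference_record> %d roots, %d measurement points\n",
              nrow(x$roots), nrow(x$points)))
  invisible(x)
}

#' Read a digitized reference record
#'
#' Tab-separated, one measurement point per row, header
#' `root_id parent_id order seq x y z d1 d2 d2_azimuth` (coordinates m,
#' diameters cm). Rows are reordered by `(root_id, seq)`.
#'
#' @param path TSV file.
#' @return a [reference_record()].
#' @export
read_reference <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file '%s' does not exist", path), call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  for (col in c("d2", "d2_azimuth"))          # all-NA columns read as logical
    if (!is.null(df[[col]])) df[[col]] <- as.numeric(df[[col]])
  reference_record(df)
}

#' Write a digitized reference record
#'
#' @param record a [reference_record()].
#' @param path output TSV file.
#' @export
write_reference <- function(record, path) {
  stopifnot(inherits(record, "reference_record"))
  utils::write.table(record$points, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Frustum volume between two measured diameters
#'
#' Volume of a conical frustum of length `l` between cross-section diameters
#' `d1` and `d2`: `pi * l / 12 * (d1^2 + d1 * d2 + d2^2)`. All arguments in
#' meters; result in cubic meters.
#'
#' @param l frustum length, m.
#' @param d1,d2 end diameters, m.
#' @export
frustum_volume <- function(l, d1, d2) {
  pi * l / 12 * (d1^2 + d1 * d2 + d2^2)
}

#' Reference traits from a digitized record
#'
#' Per root: length is the sum of Euclidean distances between consecutive
#' measurement points; volume is the sum of conical frusta between them.
#' Where a perpendicular diameter was recorded (oblong cross-section) the
#' equivalent circular diameter `sqrt(d1 * d2)` is used. Quadrant and depth
#' of length/volume follow each inter-point segment's midpoint; a root's
#' count follows its first inter-point direction (quadrant) and first
#' midpoint (depth). Roots below the proximal-diameter filter, and the
#' order-0 axis unless `include_taproot`, are excluded. Single-point roots
#' are skipped with a warning (construction forbids them, but records from
#' other tools may contain them).
#'
#' @param record a [reference_record()].
#' @param min_proximal_diam minimum proximal diameter, cm.
#' @param depth_threshold shallow/deep boundary, m.
#' @param include_taproot include the order-0 axis in totals.
#' @return a `root_traits` object (same shape as [compute_traits()]).
#' @export
reference_traits <- function(record, min_proximal_diam = 1.0,
                             depth_threshold = 0.30,
                             include_taproot = FALSE) {
  stopifnot(inherits(record, "reference_record"))
  pts <- record$points
  seg_rows <- list()
  root_rows <- list()
  for (rid in unique(pts$root_id)) {
    rp <- pts[pts$root_id == rid, , drop = FALSE]
    if (nrow(rp) < 2L) {
      warning(sprintf("root %d has a single point; skipped", rid),
              call. = FALSE)
      next
    }
    deq <- ifelse(is.na(rp$d2), rp$d1, sqrt(rp$d1 * rp$d2)) / 100  # m
    xyz <- as.matrix(rp[, c("x", "y", "z")])
    dvec <- diff(xyz)
    ell <- sqrt(rowSums(dvec^2))
    vol <- frustum_volume(ell, deq[-length(deq)], deq[-1])
    midx <- (xyz[-nrow(xyz), 1] + xyz[-1, 1]) / 2
    midy <- (xyz[-nrow(xyz), 2] + xyz[-1, 2]) / 2
    midz <- (xyz[-nrow(xyz), 3] + xyz[-1, 3]) / 2
    seg_rows[[length(seg_rows) + 1L]] <- data.frame(
      root = rid, order = rp$order[1], length = ell, volume = vol * 1000,
      quadrant = quadrant_of(midx, midy),
      depth = factor(ifelse(-midz < depth_threshold, "shallow", "deep"),
                     levels = c("shallow", "deep")))
    root_rows[[length(root_rows) + 1L]] <- data.frame(
      root = rid, order = rp$order[1], proximal_diam_cm = deq[1] * 100,
      quadrant = quadrant_of(dvec[1, 1], dvec[1, 2]),
      depth = factor(if (-midz[1] < depth_threshold) "shallow" else "deep",
                     levels = c("shallow", "deep")))
  }
  df <- do.call(rbind, seg_rows)
  pr <- do.call(rbind, root_rows)
  pr$length <- as.vector(tapply(df$length, df$root, sum)[
    as.character(pr$root)])
  pr$volume <- as.vector(tapply(df$volume, df$root, sum)[
    as.character(pr$root)])
  .aggregate_traits(df, pr, min_proximal_diam, depth_threshold,
                    include_taproot)
}

#' @rdname reference_traits
#' @export
traits_from_reference <- reference_traits
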