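#' Assign centrifugal root orders to a QSM
#'
#' The stump/taproot chain (segment 1) is order 0; every root emerging from
#' an order-k root is order k+1. Orders above 3 are lumped into 3 when
#' `lump` is set (the coarse-root convention of reporting first, second and
#' third order).
#'
#' @param qsm a [build_qsm()] result (or partially built QSM with segments).
#' @param lump lump orders > 3 into 3.
#' @return the QSM with an `order` column on `cylinders` and `segments`.
#' @export
assign_orders <- function(qsm, lump = TRUE) {
  stopifnot(inherits(qsm, "root_qsm"))
  segs <- qsm$segments
  n <- nrow(segs)
  ord <- rep(NA_integer_, n)
  if (n > 0L) {
    ord[1L] <- 0L
    repeat {
      progressed <- FALSE
      for (i in seq_len(n)) {
        if (!is.na(ord[i])) next
        p <- segs$parent[i]
        if (!is.na(p) && !is.na(ord[p])) {
          ord[i] <- ord[p] + 1L
          progressed <- TRUE
        }
      }
      if (!progressed) break
    }
    if (anyNA(ord)) {
      # roots of additional trees or a cycle: a parent chain must resolve
      reach <- function(i, seen = integer(0)) {
        while (!is.na(i)) {
          if (i %in% seen) return(TRUE)
          seen <- c(seen, i)
          i <- segs$parent[i]
        }
        FALSE
      }
      if (any(vapply(which(is.na(ord)), reach, TRUE)))
        stop("cycle detected in segment topology", call. = FALSE)
      ord[is.na(ord)] <- 1L   # orphan segments treated as first-order
    }
    if (lump) ord <- pmin(ord, 3L)
  }
  segs$order <- ord
  qsm$segments <- segs
  if (nrow(qsm$cylinders) > 0L)
    qsm$cylinders$order <- ord[match(qsm$cylinders$segment, segs$id)]
  qsm
}

#' Root traits from a QSM
#'
#' Computes length (m), volume (dm^3) and number of roots, as totals and
#' stratified by root order (1-3), cardinal quadrant (N, E, S, W) and depth
#' bin (shallow < `depth_threshold`, deep >= threshold). A "root" is a
#' maximal chain of cylinders of one order (one segment); only roots with
#' proximal diameter (twice the first cylinder's radius) of at least
#' `min_proximal_diam` cm are counted. Length and volume are apportioned
#' cylinder-wise by the quadrant/depth of each cylinder midpoint; a root's
#' count goes to the quadrant and depth of its base cylinder. The order-0
#' taproot chain is excluded from totals unless `include_taproot`.
#'
#' @param qsm a [build_qsm()] result with orders assigned.
#' @param min_proximal_diam minimum proximal diameter, cm.
#' @param depth_threshold shallow/deep boundary, m (depth 0.30 m falls in the
#'   deep bin).
#' @param include_taproot include order 0 in totals.
#' @return object of class `root_traits` with elements `totals` (named
#'   vector: `length_m`, `volume_dm3`, `number`), `by_order`, `by_quadrant`,
#'   `by_depth` (data.frames), and `per_root`.
#' @export
compute_traits <- function(qsm, min_proximal_diam = 1.0,
                           depth_threshold = 0.30, include_taproot = FALSE) {
  stopifnot(inherits(qsm, "root_qsm"))
  cyl <- qsm$cylinders
  if (nrow(cyl) == 0L) return(.empty_traits(min_proximal_diam,
                                            depth_threshold, include_taproot))
  if (is.null(cyl$order) || anyNA(cyl$order))
    stop("orders not assigned; run assign_orders()", call. = FALSE)
  mid <- cbind(cyl$start_x + cyl$axis_x * cyl$length / 2,
               cyl$start_y + cyl$axis_y * cyl$length / 2,
               cyl$start_z + cyl$axis_z * cyl$length / 2)
  df <- data.frame(
    root = cyl$segment, order = cyl$order,
    length = cyl$length, volume = pi * cyl$radius^2 * cyl$length * 1000,
    quadrant = quadrant_of(mid[, 1], mid[, 2]),
    depth = factor(ifelse(-mid[, 3] < depth_threshold, "shallow", "deep"),
                   levels = c("shallow", "deep")))
  # per-root records based on the base (first) cylinder
  base_rows <- !duplicated(cyl$segment)
  per_root <- data.frame(
    root = cyl$segment[base_rows], order = cyl$order[base_rows],
    proximal_diam_cm = 200 * cyl$radius[base_rows],
    quadrant = df$quadrant[base_rows], depth = df$depth[base_rows])
  per_root$length <- rowsum(df$length, df$root)[as.character(per_root$root), 1]
  per_root$volume <- rowsum(df$volume, df$root)[as.character(per_root$root), 1]
  .aggregate_traits(df, per_root, min_proximal_diam, depth_threshold,
                    include_taproot)
}

# shared aggregation: df has one row per cylinder/segment piece
# (root, order, length, volume, quadrant, depth); pr one row per root
# (root, order, proximal_diam_cm, quadrant, depth)
.aggregate_traits <- function(df, pr, min_proximal_diam, depth_threshold,
                              include_taproot) {
  keep_roots <- pr$root[pr$proximal_diam_cm >= min_proximal_diam &
                          (include_taproot | pr$order > 0L)]
  df <- df[df$root %in% keep_roots, , drop = FALSE]
  pr <- pr[pr$root %in% keep_roots, , drop = FALSE]

  # tapply-style sums that keep empty strata
  sum_by <- function(x, f, levels) {
    s <- tapply(x, factor(f, levels = levels), sum, default = 0)
    as.vector(ifelse(is.na(s), 0, s))
  }
  orders <- sort(unique(c(1L, 2L, 3L, pr$order)))
  if (!include_taproot) orders <- orders[orders > 0L]
  by_order <- data.frame(
    order = orders,
    length_m = sum_by(df$length, df$order, orders),
    volume_dm3 = sum_by(df$volume, df$order, orders),
    number = as.vector(table(factor(pr$order, levels = orders))))
  quads <- c("N", "E", "S", "W")
  by_quadrant <- data.frame(
    quadrant = quads,
    length_m = sum_by(df$length, df$quadrant, quads),
    volume_dm3 = sum_by(df$volume, df$quadrant, quads),
    number = as.vector(table(factor(pr$quadrant, levels = quads))))
  depths <- c("shallow", "deep")
  by_depth <- data.frame(
    depth = depths,
    length_m = sum_by(df$length, df$depth, depths),
    volume_dm3 = sum_by(df$volume, df$depth, depths),
    number = as.vector(table(factor(pr$depth, levels = depths))))
  totals <- c(length_m = sum(df$length), volume_dm3 = sum(df$volume),
              number = nrow(pr))
  structure(list(totals = totals, by_order = by_order,
                 by_quadrant = by_quadrant, by_depth = by_depth,
                 per_root = pr,
                 params = list(min_proximal_diam = min_proximal_diam,
                               depth_threshold = depth_threshold,
                               include_taproot = include_taproot)),
            class = "root_traits")
}

.empty_traits <- function(min_proximal_diam, depth_threshold,
                          include_taproot) {
  orders <- if (include_taproot) 0:3 else 1:3
  z <- function(n) numeric(n)
  structure(list(
    totals = c(length_m = 0, volume_dm3 = 0, number = 0),
    by_order = data.frame(order = orders, length_m = z(length(orders)),
                          volume_dm3 = z(length(orders)),
                          number = rep(0L, length(orders))),
    by_quadrant = data.frame(quadrant = c("N", "E", "S", "W"),
                             length_m = z(4), volume_dm3 = z(4),
                             number = rep(0L, 4)),
    by_depth = data.frame(depth = c("shallow", "deep"), length_m = z(2),
                          volume_dm3 = z(2), number = rep(0L, 2)),
    per_root = data.frame(),
    params = list(min_proximal_diam = min_proximal_diam,
                  depth_threshold = depth_threshold,
                  include_taproot = include_taproot)),
    class = "root_traits")
}

#' @export
print.root_traits <- function(x, ...) {
  cat(sprintf(
    "<root_traits> length %.2f m, volume %.3f dm^3, %d roots (>= %.1f cm)\n",
    x$totals["length_m"], x$totals["volume_dm3"], x$totals["number"],
    x$params$min_proximal_diam))
  cat("by order:\n"); print(x$by_order, row.names = FALSE)
  cat("by quadrant:\n"); print(x$by_quadrant, row.names = FALSE)
  invisible(x)
}

#' Export a trait table as CSV
#'
#' Long format with columns trait, order, quadrant, depth, value, units.
#' Stratum columns are `"all"` where a row is marginal over that stratum.
#'
#' @param traits a [compute_traits()] / [reference_traits()] result.
#' @param path output CSV file.
#' @export
export_traits <- function(traits, path) {
  stopifnot(inherits(traits, "root_traits"))
  rows <- list()
  add <- function(trait, order, quadrant, depth, value, units)
    rows[[length(rows) + 1L]] <<- data.frame(
      trait = trait, order = order, quadrant = quadrant, depth = depth,
      value = value, units = units)
  units <- c(length_m = "m", volume_dm3 = "dm3", number = "count")
  for (tr in names(units))
    add(tr, "all", "all", "all", unname(traits$totals[tr]), units[[tr]])
  for (i in seq_len(nrow(traits$by_order)))
    for (tr in names(units))
      add(tr, traits$by_order$order[i], "all", "all",
          traits$by_order[[tr]][i], units[[tr]])
  for (i in seq_len(nrow(traits$by_quadrant)))
    for (tr in names(units))
      add(tr, "all", traits$by_quadrant$quadrant[i], "all",
          traits$by_quadrant[[tr]][i], units[[tr]])
  for (i in seq_len(nrow(traits$by_depth)))
    for (tr in names(units))
      add(tr, "all", "all", traits$by_depth$depth[i],
          traits$by_depth[[tr]][i], units[[tr]])
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
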