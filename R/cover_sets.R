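#' Cover a point cloud with bounded-diameter patches
#'
#' Partitions the cloud into disjoint "cover sets" (patches) by a randomized
#' greedy ball covering: points are visited in an order shuffled by `seed`;
#' each still-uncovered point seeds a patch claiming every uncovered point
#' within `patch_diam / 2` of it. Patch extent is therefore bounded by
#' `patch_diam` by construction. Two patches are adjacent iff some
#' inter-patch point pair lies within `adjacency_factor * patch_diam`.
#' The result is deterministic given `(cloud, patch_diam, seed)`.
#'
#' @param cloud a [root_cloud()].
#' @param patch_diam patch diameter (PatchDiam), mm. The key resolution
#'   parameter of the whole reconstruction.
#' @param seed integer seed for the greedy visiting order.
#' @param adjacency_factor adjacency threshold as a multiple of `patch_diam`.
#' @param bridge_gap_factor occlusion-gap bridging: disconnected components
#'   of the patch graph are joined by minimum-distance spanning edges between
#'   patch centroids up to `bridge_gap_factor * patch_diam` apart (occlusion
#'   leaves missing connections in the neighbour relation; bridging restores
#'   a workable graph). Set to 0 to disable.
#' @return object of class `root_cover`: `patch_diam` (mm), `assignment`
#'   (patch id per point), `patches` (list of point-index sets), `centers`
#'   (patch centroids, m), `adjacency` (list of neighbour patch ids),
#'   `n_patches`, `seed`.
#' @export
generate_cover <- function(cloud, patch_diam, seed = 1L,
                           adjacency_factor = 1.0, bridge_gap_factor = 3.0) {
  stopifnot(inherits(cloud, "root_cloud"))
  .assert_scalar_pos(patch_diam, "patch_diam")
  .assert_scalar_pos(adjacency_factor, "adjacency_factor")
  n <- nrow(cloud$points)
  set.seed(as.integer(seed))
  ord <- sample.int(n)
  res <- cpp_generate_cover(cloud$points, patch_diam / 2000,
                            adjacency_factor * patch_diam / 1000, ord)
  np <- res$n_patches
  patches <- split(seq_len(n), res$patch)
  names(patches) <- NULL
  centers <- rowsum(cloud$points, res$patch) / as.vector(table(res$patch))
  edges <- res$edges
  n_bridged <- 0L
  if (bridge_gap_factor > 0 && np > 1L) {
    extra <- cpp_bridge_components(centers, edges,
                                   bridge_gap_factor * patch_diam / 1000)
    n_bridged <- nrow(extra)
    if (n_bridged > 0L) edges <- rbind(edges, extra)
  }
  adjacency <- vector("list", np)
  if (nrow(edges) > 0L) {
    a <- split(c(edges[, 2], edges[, 1]), c(edges[, 1], edges[, 2]))
    adjacency[as.integer(names(a))] <- a
  }
  adjacency[vapply(adjacency, is.null, logical(1))] <- list(integer(0))
  structure(list(patch_diam = patch_diam, assignment = res$patch,
                 patches = patches, centers = centers, adjacency = adjacency,
                 n_patches = np, seed = as.integer(seed),
                 adjacency_factor = adjacency_factor,
                 n_bridged = n_bridged),
            class = "root_cover")
}

#' @export
print.root_cover <- function(x, ...) {
  cat(sprintf(
    "<root_cover> %d patches over %d points, PatchDiam %.1f mm, seed %d\n",
    x$n_patches, length(x$assignment), x$patch_diam, x$seed))
  invisible(x)
}

.check_patch_ids <- function(cover, ids) {
  ids <- as.integer(ids)
  if (length(ids) && (anyNA(ids) || any(ids < 1L | ids > cover$n_patches)))
    stop("unknown patch id", call. = FALSE)
  ids
}

#' Expand a patch region through the adjacency graph
#'
#' Returns the "expansion layer": patches reachable from `region` in at most
#' `layers` adjacency steps, excluding `region` itself. `layers = 0` gives an
#' empty set.
#'
#' @param cover a [generate_cover()] result.
#' @param region integer vector of patch ids.
#' @param layers number of adjacency steps (>= 0).
#' @return integer vector of patch ids, sorted.
#' @export
expand_cover <- function(cover, region, layers = 1L) {
  stopifnot(inherits(cover, "root_cover"))
  region <- .check_patch_ids(cover, region)
  if (layers < 0L) stop("`layers` must be >= 0", call. = FALSE)
  if (layers == 0L || length(region) == 0L) return(integer(0))
  seen <- logical(cover$n_patches)
  seen[region] <- TRUE
  frontier <- region
  out <- integer(0)
  for (k in seq_len(layers)) {
    nxt <- unique(unlist(cover$adjacency[frontier], use.names = FALSE))
    nxt <- nxt[!seen[nxt]]
    if (length(nxt) == 0L) break
    seen[nxt] <- TRUE
    out <- c(out, nxt)
    frontier <- nxt
  }
  sort(out)
}

#' Connected components of a patch subset
#'
#' Partitions `subset` into maximal groups connected through the cover
#' adjacency restricted to `subset`. Components are ordered by their smallest
#' patch id; patches within a component are sorted.
#'
#' @param cover a [generate_cover()] result.
#' @param subset integer vector of patch ids.
#' @return list of integer vectors.
#' @export
cover_components <- function(cover, subset) {
  stopifnot(inherits(cover, "root_cover"))
  subset <- sort(unique(.check_patch_ids(cover, subset)))
  if (length(subset) == 0L) return(list())
  inset <- logical(cover$n_patches)
  inset[subset] <- TRUE
  visited <- logical(cover$n_patches)
  comps <- list()
  for (s in subset) {
    if (visited[s]) next
    comp <- integer(0)
    frontier <- s
    visited[s] <- TRUE
    while (length(frontier)) {
      comp <- c(comp, frontier)
      nxt <- unique(unlist(cover$adjacency[frontier], use.names = FALSE))
      nxt <- nxt[inset[nxt] & !visited[nxt]]
      visited[nxt] <- TRUE
      frontier <- nxt
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}
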