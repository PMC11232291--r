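#' Identify the stump / taproot region
#'
#' Operationalizes the stump as the patches whose centroids lie inside a
#' vertical cylinder around the collar axis within a depth band below the
#' collar. The cylinder radius is `radius` if given, otherwise
#' `radius_factor` times a taproot radius estimate (median horizontal
#' distance of near-collar points, inflated by 30 percent). The largest
#' connected component of the selection is returned.
#'
#' @param cover a [generate_cover()] result.
#' @param cloud the [root_cloud()] with its frame set (collar at origin,
#'   Z up).
#' @param radius_factor stump radius as a multiple of the taproot estimate.
#' @param depth depth band below the collar, m.
#' @param radius optional explicit stump radius, m.
#' @return integer vector of patch ids.
#' @export
find_stump <- function(cover, cloud, radius_factor = 1.5, depth = 0.3,
                       radius = NULL) {
  stopifnot(inherits(cover, "root_cover"))
  if (is.null(radius)) {
    # The taproot is the innermost structure at the collar. Take a thin slab
    # below the collar plane, keep points within a 0.3 m horizontal prior
    # (coarse taproots are decimetres, not metres, wide), and read the
    # taproot radius off a low quantile of the horizontal distances: taproot
    # surface points cluster tightly at the true radius while lateral-root
    # points spread far outward.
    near <- cloud$points[, 3] >= -0.03 & cloud$points[, 3] <= 0.05
    if (sum(near) < 30L)
      near <- cloud$points[, 3] >= -0.1 & cloud$points[, 3] <= 0.05
    if (!any(near))
      stop(paste("no points near the collar plane; check that set_frame()",
                 "placed the collar at the origin"), call. = FALSE)
    h <- sqrt(rowSums(cloud$points[near, 1:2, drop = FALSE]^2))
    if (any(h < 0.3)) h <- h[h < 0.3]
    radius <- radius_factor * unname(stats::quantile(h, 0.25))
  }
  ch <- sqrt(rowSums(cover$centers[, 1:2, drop = FALSE]^2))
  cz <- cover$centers[, 3]
  sel <- which(ch <= radius & cz >= -depth & cz <= 0.05)
  if (length(sel) == 0L)
    stop(paste("no patches in the stump region; check the frame",
               "(collar at origin, Z up) and stump radius"), call. = FALSE)
  comps <- cover_components(cover, sel)
  comps[[which.max(lengths(comps))]]
}

#' Detect first-order root bases by taproot expansion
#'
#' Expands the stump by `layers` layers of neighbouring patches, takes the
#' connected components of that expansion layer, and keeps those that can be
#' extended further (one more expansion step gains at least one patch outside
#' the stump and expansion layer). Each kept component is consolidated: the
#' unassigned patches of its further expansion are added, a cylinder is
#' fitted to the component's points, and only patches whose centroid lies
#' within `proximity * radius` of the cylinder surface are retained. If the
#' cylinder fit fails the component is kept unconsolidated with a warning.
#'
#' @param cover a [generate_cover()] result.
#' @param stump patch ids from [find_stump()].
#' @param cloud the [root_cloud()].
#' @param layers expansion layers (default 3).
#' @param proximity consolidation tolerance as a fraction of the fitted base
#'   radius.
#' @return list of root bases, each a list with `patches`, `axis_point`,
#'   `axis`, `radius`, `order = 1`.
#' @export
detect_root_bases <- function(cover, stump, cloud, layers = 3L,
                              proximity = 0.5) {
  stopifnot(inherits(cover, "root_cover"))
  if (length(stump) == 0L) stop("empty stump patch set", call. = FALSE)
  expl <- expand_cover(cover, stump, layers)
  if (length(expl) == 0L) return(list())
  comps <- cover_components(cover, expl)
  # the downward taproot continuation also expands the stump but is not a
  # lateral root base: drop components whose centroid stays inside the stump
  # cylinder (lateral bases extend radially outward)
  stump_h <- max(sqrt(rowSums(cover$centers[stump, 1:2, drop = FALSE]^2)))
  comps <- Filter(function(cp) {
    ctr <- colMeans(cover$centers[cp, , drop = FALSE])
    sqrt(sum(ctr[1:2]^2)) > stump_h
  }, comps)
  blocked <- logical(cover$n_patches)
  blocked[stump] <- TRUE
  blocked[expl] <- TRUE
  assigned <- logical(cover$n_patches)
  bases <- list()
  for (comp in comps) {
    further <- expand_cover(cover, comp, 1L)
    gain <- further[!blocked[further] & !assigned[further]]
    if (length(gain) == 0L) next            # not extensible: not a root base
    candidate <- sort(c(comp[!assigned[comp]], gain))
    if (length(candidate) == 0L) next
    # consolidate iteratively: fit a cylinder, keep only patches close to
    # its surface, refit. A component that welded several neighbouring
    # roots together converges onto its dominant root; the dropped patches
    # stay unassigned and are segmented as their own roots later.
    keep <- candidate
    fit <- NULL
    for (it in 1:3) {
      pts <- cloud$points[unlist(cover$patches[keep], use.names = FALSE), ,
                          drop = FALSE]
      newfit <- tryCatch(fit_cylinder(pts, if (is.null(fit)) NULL else
        fit$axis), error = function(e) NULL)
      if (is.null(newfit)) break
      fit <- newfit
      ctrs <- cover$centers[keep, , drop = FALSE]
      y <- sweep(ctrs, 2, fit$point)
      t <- as.vector(y %*% fit$axis)
      daxis <- sqrt(pmax(rowSums(y^2) - t^2, 0))
      trimmed <- keep[abs(daxis - fit$radius) <= proximity * fit$radius]
      if (length(trimmed) == 0L || length(trimmed) == length(keep)) break
      keep <- trimmed
    }
    if (is.null(fit)) {
      warning("root-base cylinder fit failed; component kept unconsolidated",
              call. = FALSE)
      keep <- candidate
      pts <- cloud$points[unlist(cover$patches[keep], use.names = FALSE), ,
                          drop = FALSE]
      ctr <- colMeans(pts)
      cen <- sweep(pts, 2, ctr)
      axis <- svd(cen, nu = 0)$v[, 1]
      radius <- stats::median(sqrt(pmax(rowSums(cen^2) -
                                          as.vector(cen %*% axis)^2, 0)))
      point <- ctr
    } else {
      axis <- fit$axis; radius <- fit$radius; point <- fit$point
    }
    assigned[keep] <- TRUE
    bases[[length(bases) + 1L]] <- list(patches = keep, axis_point = point,
                                        axis = axis, radius = radius,
                                        order = 1L)
  }
  bases
}

#' Segment the cover into root segments
#'
#' Grows segments layer by layer from the detected root bases (and from the
#' stump itself, whose continuation is the order-0 taproot chain) through
#' unassigned adjacent patches. Active segments advance in round-robin
#' lockstep. When a segment's next layer splits into several connected
#' components, the component best aligned with the segment's current
#' direction (maximal absolute cosine; ties by patch count, then smallest
#' patch id) continues the segment and the others spawn child segments with
#' their branch point recorded. Every patch is assigned to at most one
#' segment; patches unreachable from any base stay unassigned.
#'
#' @param cover a [generate_cover()] result.
#' @param bases list from [detect_root_bases()].
#' @param stump patch ids from [find_stump()].
#' @return list with `segments` (each: `id`, `layers` (list of patch-id
#'   vectors, base to tip), `parent`, `branch_patch`, `path_length`, `chord`)
#'   and `n_unassigned`.
#' @export
segment_roots <- function(cover, bases, stump) {
  stopifnot(inherits(cover, "root_cover"))
  np <- cover$n_patches
  assigned <- logical(np)
  segs <- list()
  active <- integer(0)
  newborn <- integer(0)

  new_seg <- function(first_layer, parent, branch) {
    id <- length(segs) + 1L
    segs[[id]] <<- list(id = id, layers = list(sort(first_layer)),
                        parent = parent, branch_patch = branch)
    assigned[first_layer] <<- TRUE
    newborn <<- c(newborn, id)
    id
  }
  # segment 1 is always the stump/taproot chain; the stump region is seeded
  # as a stack of depth bands (half a PatchDiam thick, collar downward) so
  # cylinder modeling walks it like any other chain
  zs <- cover$centers[stump, 3]
  band <- floor((max(zs) - zs) / (cover$patch_diam / 2000))
  stump_layers <- split(stump, band)
  new_seg(stump_layers[[1L]], NULL, NULL)
  for (k in seq_along(stump_layers)[-1L]) {
    segs[[1L]]$layers[[k]] <- sort(stump_layers[[k]])
    assigned[stump_layers[[k]]] <- TRUE
  }
  for (b in bases) {
    fresh <- b$patches[!assigned[b$patches]]
    if (length(fresh)) new_seg(fresh, 1L, NULL)
  }
  active <- newborn
  newborn <- integer(0)

  seg_dir <- function(s) {
    lay <- segs[[s]]$layers
    k <- length(lay)
    ctr_last <- colMeans(cover$centers[lay[[k]], , drop = FALSE])
    back <- max(1L, k - 3L)
    ctr_back <- colMeans(cover$centers[lay[[back]], , drop = FALSE])
    d <- ctr_last - ctr_back
    if (sqrt(sum(d^2)) < 1e-12) c(0, 0, -1) else .unit(d)
  }

  while (length(active)) {
    still <- integer(0)
    for (s in active) {
      last <- segs[[s]]$layers[[length(segs[[s]]$layers)]]
      nxt <- unique(unlist(cover$adjacency[last], use.names = FALSE))
      nxt <- nxt[!assigned[nxt]]
      if (length(nxt) == 0L) next
      comps <- cover_components(cover, nxt)
      if (length(comps) > 1L)
        comps <- .persistent_components(cover, comps, assigned)
      if (length(comps) == 1L) {
        assigned[comps[[1L]]] <- TRUE
        segs[[s]]$layers[[length(segs[[s]]$layers) + 1L]] <- comps[[1L]]
        still <- c(still, s)
        next
      }
      dir <- seg_dir(s)
      ctr_last <- colMeans(cover$centers[last, , drop = FALSE])
      score <- vapply(comps, function(cp) {
        d <- colMeans(cover$centers[cp, , drop = FALSE]) - ctr_last
        nd <- sqrt(sum(d^2))
        if (nd < 1e-12) return(-1)
        abs(sum(d * dir) / nd)
      }, 0)
      sizes <- lengths(comps)
      minid <- vapply(comps, min, 0L)
      if (s == 1L) {
        # the taproot is the axial structure: its chain continues with the
        # component nearest the collar axis, not the best-aligned one (a
        # steeply diving lateral can out-align the true continuation)
        hdist <- vapply(comps, function(cp)
          sqrt(sum(colMeans(cover$centers[cp, , drop = FALSE])[1:2]^2)), 0)
        cont <- order(hdist, -sizes, minid)[1L]
      } else
      cont <- order(-score, -sizes, minid)[1L]
      for (ci in seq_along(comps)) {
        if (ci == cont) {
          assigned[comps[[ci]]] <- TRUE
          segs[[s]]$layers[[length(segs[[s]]$layers) + 1L]] <- comps[[ci]]
        } else {
          branch <- .branch_patch(cover, last, comps[[ci]])
          new_seg(comps[[ci]], s, branch)
        }
      }
      still <- c(still, s)
    }
    active <- c(still, newborn)
    newborn <- integer(0)
  }

  segs <- lapply(segs, function(s) {
    ctrs <- t(vapply(s$layers, function(l)
      colMeans(cover$centers[l, , drop = FALSE]), numeric(3)))
    s$layer_ctrs <- ctrs
    s$path_length <- if (nrow(ctrs) > 1L)
      sum(sqrt(rowSums(diff(ctrs)^2))) else 0
    s$chord <- if (nrow(ctrs) > 1L)
      sqrt(sum((ctrs[nrow(ctrs), ] - ctrs[1L, ])^2)) else 0
    s
  })
  list(segments = segs, n_unassigned = sum(!assigned))
}

# Persistence check for layer splits: components of the next layer that
# reconnect through still-unassigned patches within `lookahead` adjacency
# steps are transient (noise/occlusion artefacts wrapping around the root)
# and are merged back together; only persistent components spawn branches.
.persistent_components <- function(cover, comps, assigned, lookahead = 2L) {
  k <- length(comps)
  reach <- vector("list", k)
  for (i in seq_len(k)) {
    seen <- logical(cover$n_patches)
    seen[comps[[i]]] <- TRUE
    frontier <- comps[[i]]
    for (step in seq_len(lookahead)) {
      nb <- unique(unlist(cover$adjacency[frontier], use.names = FALSE))
      nb <- nb[!seen[nb] & !assigned[nb]]
      if (length(nb) == 0L) break
      seen[nb] <- TRUE
      frontier <- nb
    }
    reach[[i]] <- which(seen)
  }
  # union components whose reach sets intersect
  grp <- seq_len(k)
  find <- function(x) { while (grp[x] != x) x <- grp[x]; x }
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      if (find(i) != find(j) && length(intersect(reach[[i]],
                                                 reach[[j]])) > 0L)
        grp[find(j)] <- find(i)
    }
  }
  groups <- split(seq_len(k), vapply(seq_len(k), find, 0L))
  lapply(groups, function(g)
    sort(unique(unlist(comps[g], use.names = FALSE))))
}

# smallest patch in `last` adjacent to the component
.branch_patch <- function(cover, last, comp) {
  inc <- logical(cover$n_patches)
  inc[comp] <- TRUE
  for (p in sort(last)) {
    if (any(inc[cover$adjacency[[p]]])) return(p)
  }
  min(last)
}

#' Merge segments across branch points
#'
#' A child segment whose branch point lies at its parent's tip is merged into
#' the parent when the merged chain keeps `chord / path >= straightness`
#' (segments "as long as possible while staying close to straight"). Among
#' qualifying tip children of a parent the straightest merged result wins;
#' the procedure iterates to a fixed point and re-links topology.
#'
#' @param segmentation result of [segment_roots()].
#' @param straightness minimal chord/path ratio (default 0.9).
#' @return a segmentation list of the same shape.
#' @export
merge_segments <- function(segmentation, straightness = 0.9) {
  segs <- segmentation$segments
  alive <- rep(TRUE, length(segs))
  parent_of <- vapply(segs, function(s) s$parent %||% NA_integer_, 0L)

  repeat {
    merged_any <- FALSE
    for (p in seq_along(segs)) {
      if (!alive[p]) next
      tip_layer <- segs[[p]]$layers[[length(segs[[p]]$layers)]]
      kids <- which(alive & !is.na(parent_of) & parent_of == p)
      kids <- kids[vapply(kids, function(k)
        !is.null(segs[[k]]$branch_patch) &&
          segs[[k]]$branch_patch %in% tip_layer, TRUE)]
      if (length(kids) == 0L) next
      ratios <- vapply(kids, function(k)
        .merged_ratio(segs[[p]], segs[[k]]), 0)
      ok <- ratios >= straightness
      if (!any(ok)) next
      k <- kids[ok][which.max(ratios[ok])]
      segs[[p]]$layers <- c(segs[[p]]$layers, segs[[k]]$layers)
      segs[[p]]$layer_ctrs <- rbind(segs[[p]]$layer_ctrs,
                                    segs[[k]]$layer_ctrs)
      parent_of[parent_of == k] <- p
      for (j in which(alive & !is.na(parent_of) & parent_of == p)) {
        if (j != k) segs[[j]]$parent <- p
      }
      alive[k] <- FALSE
      merged_any <- TRUE
    }
    if (!merged_any) break
  }
  kept <- segs[alive]
  idmap <- stats::setNames(seq_along(kept),
                           vapply(kept, function(s) s$id, 0L))
  keptids <- which(alive)
  kept <- lapply(seq_along(kept), function(i) {
    s <- kept[[i]]
    s$id <- i
    op <- parent_of[keptids[i]]
    s$parent <- if (is.na(op)) NULL else unname(idmap[as.character(op)])
    ctrs <- s$layer_ctrs
    if (nrow(ctrs) > 1L) {
      s$path_length <- sum(sqrt(rowSums(diff(ctrs)^2)))
      s$chord <- sqrt(sum((ctrs[nrow(ctrs), ] - ctrs[1L, ])^2))
    } else {
      s$path_length <- 0; s$chord <- 0
    }
    s
  })
  segmentation$segments <- kept
  segmentation
}

# chord/path ratio of a parent+child merged chain from stored layer centroids
.merged_ratio <- function(pseg, kseg) {
  ctrs <- rbind(pseg$layer_ctrs, kseg$layer_ctrs)
  path <- sum(sqrt(rowSums(diff(ctrs)^2)))
  if (path < 1e-12) return(1)
  sqrt(sum((ctrs[nrow(ctrs), ] - ctrs[1L, ])^2)) / path
}
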