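# independent re-implementation of the greedy covering rule
greedy_cover_oracle <- function(pts, patch_diam_mm, seed) {
  n <- nrow(pts)
  set.seed(seed)
  ord <- sample.int(n)
  r <- patch_diam_mm / 2000
  patch <- integer(n)
  np <- 0L
  for (i in ord) {
    if (patch[i] > 0L) next
    np <- np + 1L
    d <- sqrt(colSums((t(pts) - pts[i, ])^2))
    patch[d <= r & patch == 0L] <- np
  }
  list(patch = patch, n = np)
}

test_that("degenerate covers: single point and far-apart points", {
  cl <- root_cloud(matrix(c(0, 0, 0), 1))
  cv <- generate_cover(cl, 25)
  expect_equal(cv$n_patches, 1L)
  expect_equal(cv$adjacency[[1]], integer(0))

  two <- root_cloud(rbind(c(0, 0, 0), c(1, 0, 0)))
  cv2 <- generate_cover(two, 25, bridge_gap_factor = 3)
  expect_equal(cv2$n_patches, 2L)
  expect_equal(cv2$adjacency[[1]], integer(0))  # 1 m apart, no adjacency
})

test_that("greedy covering matches a brute-force oracle on a line", {
  pts <- cbind(seq(0, 0.99, by = 0.01), 0, 0)    # 100 points, 10 mm spacing
  cl <- root_cloud(pts)
  counts <- integer(10)
  for (s in 1:10) {
    cv <- generate_cover(cl, 25, seed = s)
    orc <- greedy_cover_oracle(pts, 25, s)
    expect_equal(cv$n_patches, orc$n)
    expect_equal(cv$assignment, orc$patch)
    counts[s] <- cv$n_patches
  }
  expect_true(all(counts >= 34 & counts <= 50))
})

test_that("covers partition the cloud with bounded patch extent", {
  set.seed(11)
  pts <- matrix(runif(900, 0, 0.3), ncol = 3)
  cl <- root_cloud(pts)
  for (pd in c(10, 30, 80)) {
    for (s in 1:2) {
      cv <- generate_cover(cl, pd, seed = s)
      idx <- sort(unlist(cv$patches))
      expect_equal(idx, seq_len(nrow(pts)))        # disjoint + exhaustive
      ext <- vapply(cv$patches, function(i)
        if (length(i) < 2) 0 else max(dist(pts[i, ])), 0)
      expect_true(all(ext <= pd / 1000 + 1e-12))
      # adjacency symmetric and irreflexive
      for (p in seq_len(cv$n_patches)) {
        expect_false(p %in% cv$adjacency[[p]])
        for (q in cv$adjacency[[p]]) expect_true(p %in% cv$adjacency[[q]])
      }
    }
  }
})

test_that("patch count is non-increasing across the default grid", {
  sc <- small_scan()
  sub <- root_cloud(sc$cloud$points[seq(1, nrow(sc$cloud$points), by = 4), ])
  counts <- vapply(default_patchdiam_grid(), function(pd)
    generate_cover(sub, pd, seed = 5)$n_patches, 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("adjacency graph is connected on a densely sampled cylinder", {
  pts <- cylinder_points(8000, radius = 0.03, length = 0.5)
  cv <- generate_cover(root_cloud(pts), 20, seed = 1, bridge_gap_factor = 0)
  comps <- cover_components(cv, seq_len(cv$n_patches))
  expect_equal(length(comps), 1L)
})

test_that("expansion layers follow graph reachability", {
  # path graph a-b-c-d
  cv <- fake_cover(list(2L, c(1L, 3L), c(2L, 4L), 3L))
  expect_equal(expand_cover(cv, 1L, 0L), integer(0))
  expect_equal(expand_cover(cv, 1L, 2L), c(2L, 3L))
  expect_error(expand_cover(cv, 9L, 1L), "unknown patch")

  # BFS-oracle property on random graphs: expand(k) subset of
  # expand(k+1) + region, and equals breadth-first distance k reachability
  set.seed(12)
  for (rep in 1:5) {
    n <- 30L
    adj <- lapply(seq_len(n), function(i) integer(0))
    for (e in 1:60) {
      ij <- sample.int(n, 2)
      adj[[ij[1]]] <- sort(unique(c(adj[[ij[1]]], ij[2])))
      adj[[ij[2]]] <- sort(unique(c(adj[[ij[2]]], ij[1])))
    }
    cv <- fake_cover(adj)
    region <- sample.int(n, 3)
    # reference BFS distances
    dist <- rep(Inf, n); dist[region] <- 0
    frontier <- region
    d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- setdiff(unique(unlist(adj[frontier])), which(is.finite(dist)))
      dist[nxt] <- d
      frontier <- nxt
    }
    for (k in 0:3) {
      ek <- expand_cover(cv, region, k)
      expect_equal(ek, sort(which(dist >= 1 & dist <= k)))
      expect_true(all(ek %in% c(expand_cover(cv, region, k + 1L), region)))
    }
  }
})

test_that("connected components match a union-find oracle", {
  expect_equal(cover_components(fake_cover(list(integer(0))), integer(0)),
               list())
  cv2 <- fake_cover(list(integer(0), integer(0)))
  expect_equal(cover_components(cv2, 1:2), list(1L, 2L))

  set.seed(13)
  for (rep in 1:5) {
    n <- 50L
    adj <- lapply(seq_len(n), function(i) integer(0))
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    for (e in 1:40) {
      ij <- sample.int(n, 2)
      adj[[ij[1]]] <- sort(unique(c(adj[[ij[1]]], ij[2])))
      adj[[ij[2]]] <- sort(unique(c(adj[[ij[2]]], ij[1])))
      parent[find(ij[1])] <- find(ij[2])
    }
    lab <- vapply(seq_len(n), find, 0L)
    oracle <- unname(split(seq_len(n), lab))
    oracle <- oracle[order(vapply(oracle, min, 0L))]
    got <- cover_components(fake_cover(adj), seq_len(n))
    expect_equal(got, lapply(oracle, as.integer))
  }
})
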