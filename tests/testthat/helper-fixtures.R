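## Shared fixtures and independent oracles. Expensive fixtures are built
## lazily and cached for the whole test run.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

## straight cable along +x: n nodes, total length `len`
cable_tree <- function(n = 11, len = 100, radius = 1) {
  morph_tree(data.frame(
    id = seq_len(n), label = c("soma", rep("basal", n - 1)),
    x = seq(0, len, length.out = n), y = 0, z = 0,
    radius = radius, parent = c(-1L, seq_len(n - 1))))
}

## Y-shaped tree: stem of length a, two branches of length b each, in-plane
y_tree <- function(a = 10, b = 10) {
  morph_tree(data.frame(
    id = 1:4, label = c("soma", "basal", "basal", "basal"),
    x = c(0, a, a + b / sqrt(2), a + b / sqrt(2)),
    y = c(0, 0, b / sqrt(2), -b / sqrt(2)), z = 0,
    radius = c(2, 1, 1, 1), parent = c(-1L, 1L, 2L, 2L)))
}

## radial star: k straight spokes from the root
star_tree <- function(k = 12, len = 50, nodes_per_spoke = 10) {
  rows <- list(data.frame(id = 1L, label = "soma", x = 0, y = 0, z = 0,
                          radius = 3, parent = -1L))
  nid <- 1L
  for (s in seq_len(k)) {
    th <- 2 * pi * s / k
    prev <- 1L
    for (j in seq_len(nodes_per_spoke)) {
      nid <- nid + 1L
      r <- len * j / nodes_per_spoke
      rows[[length(rows) + 1L]] <-
        data.frame(id = nid, label = "basal", x = r * cos(th),
                   y = r * sin(th), z = 0, radius = 1, parent = prev)
      prev <- nid
    }
  }
  morph_tree(do.call(rbind, rows))
}

## classical Euclidean MST total length (Prim), independent of grow_mst
prim_mst_length <- function(P) {
  n <- nrow(P)
  D <- as.matrix(stats::dist(P))
  in_tree <- c(1L)
  total <- 0
  while (length(in_tree) < n) {
    out <- setdiff(seq_len(n), in_tree)
    sub <- D[in_tree, out, drop = FALSE]
    m <- min(sub)
    total <- total + m
    j <- out[which(apply(sub, 2, min) == m)[1]]
    in_tree <- c(in_tree, j)
  }
  total
}

## brute-force recount of branch statistics by walking the adjacency
recount_stats <- function(tree) {
  nd <- tree$nodes
  n <- nrow(nd)
  kids <- lapply(seq_len(n), function(i) which(nd$parent == i))
  deg <- lengths(kids)
  xyz <- as.matrix(nd[, c("x", "y", "z")])
  tot <- 0
  for (i in seq_len(n)) if (nd$parent[i] > 0)
    tot <- tot + sqrt(sum((xyz[i, ] - xyz[nd$parent[i], ])^2))
  n_bp <- sum(deg >= 2 & seq_len(n) >= 1)
  ## segments: walk from each termination/branch end up to previous topo pt
  ends <- which(deg == 0 | (deg >= 2 & seq_len(n) != 1L))
  ends <- setdiff(ends, 1L)
  n_seg <- length(ends)
  list(n_branch_points = n_bp, total_length = tot, n_segments = n_seg)
}

## brute-force discrete Frechet by enumerating all monotone couplings
frechet_brute <- function(P, Q) {
  n <- nrow(P); m <- nrow(Q)
  d <- function(i, j) sqrt(sum((P[i, ] - Q[j, ])^2))
  best <- Inf
  rec <- function(i, j, cur) {
    cur <- max(cur, d(i, j))
    if (cur >= best) return()
    if (i == n && j == m) { best <<- min(best, cur); return() }
    if (i < n) rec(i + 1, j, cur)
    if (j < m) rec(i, j + 1, cur)
    if (i < n && j < m) rec(i + 1, j + 1, cur)
  }
  rec(1, 1, 0)
  best
}

## small random morphology grown in a sphere (shared across tests)
small_sphere_tree <- function(seed = 1) {
  fixture(paste0("sph", seed), function()
    make_synthetic_tree("sphere", N = 60, bf = 0.4, seed = seed, radius = 80))
}

classIV_fixture <- function() fixture("classIV", function() make_classIV_like(seed = 42))
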