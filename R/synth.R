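## Synthetic-morphology generators: stand-in arbours for tests, demos and
## the balancing-factor calibration. Parameters target the qualitative
## regimes of real cells (flat dense space-filling arbours versus sparse
## radial ones), not any specific specimen.

.sample_shape <- function(shape, N, radius) {
  switch(shape,
    disc2D = {
      r <- radius * sqrt(stats::runif(N))
      th <- stats::runif(N, 0, 2 * pi)
      cbind(r * cos(th), r * sin(th), 0)
    },
    sphere = {
      r <- radius * stats::runif(N)^(1 / 3)
      u <- stats::rnorm(N); v <- stats::rnorm(N); w <- stats::rnorm(N)
      nrm <- sqrt(u^2 + v^2 + w^2)
      cbind(r * u / nrm, r * v / nrm, r * w / nrm)
    },
    cone = {                       # apex at origin, axis +y, height 2*radius
      h <- 2 * radius
      yy <- h * stats::runif(N)^(1 / 3)
      rr <- 0.5 * yy * sqrt(stats::runif(N))
      th <- stats::runif(N, 0, 2 * pi)
      cbind(rr * cos(th), yy, rr * sin(th))
    },
    slab = cbind(stats::runif(N, -radius, radius),
                 stats::runif(N, -radius, radius),
                 stats::runif(N, -0.1 * radius, 0.1 * radius)),
    stop("unknown volume shape: ", shape))
}

#' Generate a synthetic dendritic arbour
#'
#' Distributes `N` uniform target points in a simple shape, grows a tree
#' from a central soma with the optimal-wiring rule ([grow_mst()]) at the
#' given balancing factor, resamples to uniform node spacing and applies a
#' default quadratic diameter taper. Deterministic per seed.
#'
#' @param volume_shape one of `"disc2D"`, `"sphere"`, `"cone"`, `"slab"`
#' @param N number of target points
#' @param bf balancing factor in `[0, 1]`
#' @param seed integer seed
#' @param radius shape scale, um (disc/sphere radius; cone height is
#'   `2 * radius`; slab half-width)
#' @param soma_radius soma radius, um
#' @param spacing resampling spacing, um
#' @param taper apply the default diameter taper (set `FALSE` to keep
#'   placeholder radii)
#' @return a [morph_tree()]
#' @export
make_synthetic_tree <- function(volume_shape = c("disc2D", "sphere", "cone",
                                                 "slab"),
                                N = 200, bf = 0.5, seed = 1L, radius = 100,
                                soma_radius = 5, spacing = 1, taper = TRUE) {
  volume_shape <- match.arg(volume_shape)
  seed <- as.integer(seed)
  .with_seed(seed, {
    targets <- .sample_shape(volume_shape, N, radius)
    root <- morph_tree(data.frame(id = 1L, label = "soma", x = 0, y = 0,
                                  z = 0, radius = soma_radius, parent = -1L))
    g <- grow_mst(root, targets, bf = bf, G_thr = Inf)
    tr <- resample_tree(g$tree, spacing)
    if (taper) {
      new_ids <- setdiff(seq_len(n_nodes(tr)), 1L)
      tr <- apply_taper(tr, new_ids,
                        list(scale = 1.2, offset = 0.4, d_min = 0.3))
    }
    tr$provenance <- sprintf("synthetic %s (N=%d, bf=%.2f, seed=%d)",
                             volume_shape, N, bf, seed)
    tr
  })
}

#' Generate a flat, dense, space-filling arbour
#'
#' A stand-in for the planar dendritic-arborisation class IV sensory
#' neurons of Drosophila larvae, which tile a two-dimensional receptive
#' field densely with a low balancing factor: a 200 um disc filled from 800
#' target points at bf = 0.2.
#'
#' @param seed integer seed
#' @return a [morph_tree()]
#' @export
make_classIV_like <- function(seed = 1L) {
  make_synthetic_tree("disc2D", N = 800, bf = 0.2, seed = seed, radius = 200,
                      soma_radius = 3)
}

#' Generate a pyramidal-like arbour with basal and apical trees
#'
#' A soma with a spherical basal tree (bf = 0.7) plus an apical tree built
#' from a straight main trunk and oblique branches grown in a cone around
#' it — the geometry the main-growth repair option is designed for.
#'
#' @param seed integer seed
#' @return a [morph_tree()] with both `basal` and `apical` labels
#' @export
make_pyramidal_like <- function(seed = 1L) {
  .with_seed(seed, {
    trunk_len <- 250L
    nodes <- data.frame(id = 1L, label = "soma", x = 0, y = 0, z = 0,
                        radius = 6, parent = -1L)
    tr <- morph_tree(nodes)
    ## straight apical trunk along +y
    trunk <- data.frame(id = 1L + seq_len(trunk_len / 5), label = "apical",
                        x = 0, y = 5 * seq_len(trunk_len / 5), z = 0,
                        radius = 1.8,
                        parent = c(1L, 1L + seq_len(trunk_len / 5 - 1)),
                        cut = FALSE)
    tr <- morph_tree(rbind(tr$nodes, trunk))
    trunk_ids <- 2:n_nodes(tr)
    ## basal tree in a sphere around the soma
    basal_t <- .sample_shape("sphere", 120, 80)
    basal_t <- basal_t[basal_t[, 2] < 40, , drop = FALSE]
    g <- grow_mst(tr, basal_t, bf = 0.7, G_thr = Inf, attach_ids = 1L)
    tr <- g$tree
    ## oblique apical branches in a cone around the upper trunk
    obl <- .sample_shape("cone", 80, 100)
    obl[, 2] <- obl[, 2] * 0.75 + 60
    g <- grow_mst(tr, obl, bf = 0.7, G_thr = Inf, attach_ids = trunk_ids)
    tr <- resample_tree(g$tree, 1)
    tr <- apply_taper(tr, setdiff(seq_len(n_nodes(tr)), 1L),
                      list(scale = 2.2, offset = 0.5, d_min = 0.3))
    tr$provenance <- sprintf("synthetic pyramidal-like (seed=%d)", seed)
    tr
  })
}

#' Small hand-coded 2D demo morphology with designated cut branches
#'
#' A fixed miniature planar tree whose two designated terminals are flagged
#' as cut ends; used in documentation and smoke tests of the repair
#' pipeline (repairs at bf = 0 and bf = 1 produce visibly different
#' topologies on it).
#'
#' @return list with `tree` (a [morph_tree()], cut flags set) and `cut_ids`
#' @export
make_demo_2d <- function() {
  ## soma at origin, two stems; terminals 7 and 12 are incomplete ends
  nd <- data.frame(
    id = 1:12,
    label = c("soma", rep("basal", 11)),
    x = c(0, 10, 20, 30, 30, 40, 50, -10, -20, -30, -30, -40),
    y = c(0, 0, 0, 10, -10, 15, -15, 0, 5, 15, -10, 20),
    z = 0,
    radius = c(5, 1.6, 1.4, 1.2, 1.2, 1.0, 1.0, 1.6, 1.4, 1.2, 1.0, 1.0),
    parent = c(-1L, 1L, 2L, 3L, 3L, 4L, 5L, 1L, 8L, 9L, 9L, 10L),
    cut = FALSE)
  nd$cut[nd$id %in% c(7L, 12L)] <- TRUE
  tree <- morph_tree(nd, provenance = "hand-coded 2D demo")
  list(tree = tree, cut_ids = which(tree$nodes$cut))
}
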