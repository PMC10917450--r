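## fix_tree orchestration: parameter estimation from the input neuron,
## target-point distribution in the growth volume, mode-constrained growth,
## branch-point matching, and post-processing (jitter, taper, pruning).

.dr_cache <- new.env(parent = emptyenv())

## Calibration curve mapping mean root angle -> balancing factor.
## Reference trees are grown across a bf grid in a matched normalised volume
## (disc or sphere of radius 100 um, 150 targets, fixed internal seeds); the
## mean root angle decreases monotonically with bf, and the inverse of the
## isotonic fit of that curve is the estimator.
.bf_calibration <- function(is2d) {
  key <- if (is2d) "cal2d" else "cal3d"
  if (!is.null(.dr_cache[[key]])) return(.dr_cache[[key]])
  grid <- seq(0, 1, by = 0.1)
  angs <- vapply(grid, function(b) {
    mean(vapply(1:5, function(s) {
      tr <- make_synthetic_tree(if (is2d) "disc2D" else "sphere",
                                N = 150, bf = b, seed = 1000L + s,
                                radius = 100, taper = FALSE)
      mean(root_angle_distribution(tr))
    }, numeric(1)))
  }, numeric(1))
  ## enforce monotone non-increasing angle in bf
  iso <- stats::isoreg(grid, -angs)
  fit <- -iso$yf
  cal <- list(bf = grid, angle = fit)
  .dr_cache[[key]] <- cal
  cal
}

.is_planar <- function(tree) {
  xyz <- node_xyz(tree)
  ext <- apply(xyz, 2, function(v) diff(range(v)))
  ext[3] <= 1e-6 * max(ext, 1)
}

#' Estimate the balancing factor of a morphology
#'
#' Inverts a precomputed calibration curve between the balancing factor and
#' the mean of the root-angle distribution: trees grown with high `bf` run
#' radially (small root angles), trees grown with low `bf` meander to save
#' cable (large root angles). The calibration is generated once per session
#' by growing reference trees across a `bf` grid (0, 0.1, ..., 1) in a
#' matched normalised volume and is dimension-aware (flat arbours use a 2D
#' calibration).
#'
#' @param tree a [morph_tree()], resampled to uniform spacing (see
#'   [resample_tree()]); at least 20 nodes.
#' @return estimated balancing factor in `[0, 1]`
#' @export
estimate_bf <- function(tree) {
  if (n_nodes(tree) < 20) {
    warning("fewer than 20 nodes: falling back to bf = 0.5")
    return(0.5)
  }
  ang <- mean(root_angle_distribution(tree))
  cal <- .bf_calibration(.is_planar(tree))
  ## angle decreases in bf; invert with clamping at the calibration range
  o <- order(cal$angle)
  est <- stats::approx(cal$angle[o], cal$bf[o], xout = ang, rule = 2,
                       ties = mean)$y
  min(1, max(0, est))
}

#' Growth threshold from the growth-volume chord
#'
#' The growth threshold `G_thr` bounds the Euclidean span of any single new
#' connection. It is derived from the geometry of the growth volume: take
#' `Q`, the midpoint between the centroid of the volume's defining points and
#' the defining point farthest from the neuron root `R`; `G_thr` is the total
#' chord length of the straight line through `R` and `Q` inside the volume.
#'
#' @param volume a [growth_volume()]
#' @param root numeric 3-vector: position of the neuron root (soma), um
#' @return `G_thr` in micrometres
#' @export
growth_threshold <- function(volume, root) {
  root <- as.numeric(root)
  pts <- volume$points
  v_mean <- colMeans(pts)
  d_root <- sqrt(colSums((t(pts) - root)^2))
  v_far <- pts[which.max(d_root), ]
  q <- (v_mean + v_far) / 2
  dir <- q - root
  if (sqrt(sum(dir^2)) < 1e-9) dir <- v_far - root
  g <- gv_chord_length(volume, root, dir)
  if (g <= 0)
    stop("the line through the root and the volume midpoint misses the ",
         "growth volume; set G_thr manually in growth_params()")
  g
}

#' Estimate the number of target points for a growth volume
#'
#' Scales the density of topological points (branch points plus
#' terminations) of the input neuron, measured over its spanning-field
#' convex hull, to the size of the growth volume, at two target points per
#' expected topological point (branch-point matching later corrects the
#' level; this only sets the starting point). Never returns less than 1.
#'
#' @param tree a [morph_tree()] (the input neuron)
#' @param volume a [growth_volume()]
#' @return integer number of target points
#' @export
estimate_target_count <- function(tree, volume) {
  n_topo <- length(branch_point_ids(tree)) + length(terminal_ids(tree))
  hull_measure <- tryCatch(gv_measure(growth_volume(node_xyz(tree), alpha = 0)),
                           error = function(e) NA_real_)
  if (!is.finite(hull_measure) || hull_measure <= 0) {
    ext <- apply(node_xyz(tree), 2, function(v) diff(range(v)))
    hull_measure <- prod(pmax(ext[ext > 1e-9], 1))
  }
  rho <- n_topo / hull_measure
  max(1L, as.integer(round(2 * rho * gv_measure(volume))))
}

#' Distribute target points in a growth volume
#'
#' Monte Carlo rejection sampling: candidate points are drawn uniformly in
#' the volume's bounding box, kept if they fall inside the volume, lie at
#' least `R_d` from every exclusion point, and pass a density acceptance
#' test against a Gaussian kernel-density weight built from `density_points`
#' (typically the branch and termination points of the input neuron, so new
#' targets cluster the way the existing arbour does). With
#' `density_points = NULL` the distribution is uniform over the volume.
#'
#' @param volume a [growth_volume()]
#' @param npts number of points to place (>= 1)
#' @param density_points optional `k x 3` matrix steering the point density
#' @param exclusion optional `k x 3` matrix of points targets must avoid
#' @param R_d exclusion margin, um
#' @param seed integer seed (sampling is reproducible given the seed)
#' @param max_tries attempt budget per requested point before giving up
#' @return `npts x 3` matrix of target points
#' @export
distribute_targets <- function(volume, npts, density_points = NULL,
                               exclusion = NULL, R_d = 0, seed = 1L,
                               max_tries = 2000L) {
  npts <- as.integer(npts)
  if (npts < 1) stop("npts must be >= 1")
  pts <- volume$points
  lo <- apply(pts, 2, min); hi <- apply(pts, 2, max)
  if (volume$is2d) { lo[3] <- volume$z0; hi[3] <- volume$z0 }
  if (!is.null(density_points)) {
    density_points <- as.matrix(density_points)
    if (ncol(density_points) == 2) density_points <- cbind(density_points, 0)
    if (nrow(density_points) < 5) density_points <- NULL  # too few: uniform
  }
  if (!is.null(density_points)) {
    d <- if (volume$is2d) 2 else 3
    sds <- apply(density_points, 2, stats::sd)
    h <- max(1.06 * mean(sds[1:d], na.rm = TRUE) *
               nrow(density_points)^(-1 / (d + 4)), 1e-6)
    if (!is.finite(h)) {
      density_points <- NULL
    } else {
      kde_w <- function(q) {
        d2 <- outer(rowSums(q^2), rowSums(density_points^2), "+") -
          2 * q %*% t(density_points)
        rowSums(exp(-pmax(d2, 0) / (2 * h^2)))
      }
      w_max <- max(kde_w(density_points))
    }
  }
  if (!is.null(exclusion)) {
    exclusion <- as.matrix(exclusion)
    if (ncol(exclusion) == 2) exclusion <- cbind(exclusion, 0)
  }
  .with_seed(seed, {
    out <- matrix(numeric(0), 0, 3)
    tries <- 0L
    budget <- max_tries * npts
    while (nrow(out) < npts) {
      chunk <- max(256L, 4L * npts)
      if (tries >= budget)
        stop("could not place ", npts, " target points (volume too small, ",
             "or fully excluded by R_d = ", R_d, ")")
      tries <- tries + chunk
      q <- cbind(stats::runif(chunk, lo[1], hi[1]),
                 stats::runif(chunk, lo[2], hi[2]),
                 stats::runif(chunk, lo[3], hi[3]))
      keep <- gv_contains(volume, q)
      q <- q[keep, , drop = FALSE]
      if (nrow(q) > 0 && !is.null(exclusion) && R_d > 0) {
        d2 <- outer(rowSums(q^2), rowSums(exclusion^2), "+") -
          2 * q %*% t(exclusion)
        q <- q[sqrt(pmax(apply(d2, 1, min), 0)) >= R_d, , drop = FALSE]
      }
      if (nrow(q) > 0 && !is.null(density_points)) {
        acc <- stats::runif(nrow(q)) < kde_w(q) / w_max
        q <- q[acc, , drop = FALSE]
      }
      if (nrow(q) > 0) out <- rbind(out, q)
    }
    out[seq_len(npts), , drop = FALSE]
  })
}

#' Identify the cut (incomplete) terminals relevant to a growth volume
#'
#' Returns the cut-flagged terminals whose distance to the volume is at most
#' 10% of the tree's bounding-box diagonal (the tolerated distance between an
#' incomplete end and the volume scales with the size of the input tree). If
#' the tree carries no cut flags, a heuristic is applied with a warning:
#' terminals near the volume whose radius exceeds the median terminal radius
#' (cut ends of real reconstructions are conspicuously thick for a terminal).
#'
#' @param tree a [morph_tree()]
#' @param volume a [growth_volume()]
#' @return integer vector of terminal node ids (possibly empty)
#' @export
find_cut_terminals <- function(tree, volume) {
  xyz <- node_xyz(tree)
  diag_len <- sqrt(sum(apply(xyz, 2, function(v) diff(range(v)))^2))
  thr <- 0.1 * diag_len
  flagged <- which(tree$nodes$cut)
  if (length(flagged) > 0) {
    d <- gv_distance(volume, xyz[flagged, , drop = FALSE])
    return(flagged[d <= thr])
  }
  terms <- terminal_ids(tree)
  if (length(terms) == 0) return(integer(0))
  d <- gv_distance(volume, xyz[terms, , drop = FALSE])
  near <- terms[d <= thr]
  med <- stats::median(tree$nodes$radius[terms])
  sel <- near[tree$nodes$radius[near] > med]
  if (length(sel) > 0)
    warning("no cut-flagged terminals; using ", length(sel),
            " thick terminal(s) near the volume as putative cut ends")
  sel
}

#' Grow a main (apical-style) branch from the thickest cut terminal
#'
#' Pyramidal neurons feature one or more prominent main apical dendrites
#' running roughly straight away from the soma. When main growth is enabled,
#' a polyline of `spacing`-sized steps is appended to the thickest cut
#' terminal along the direction of the line through the root and the volume
#' midpoint `Q` (the same line that defines the growth threshold), until 95%
#' of `G_thr` is covered or the next step would leave the volume. New nodes
#' are labelled `apical`.
#'
#' @param tree a [morph_tree()]
#' @param volume a [growth_volume()]
#' @param cut_ids candidate cut terminals (non-empty); see
#'   [find_cut_terminals()]
#' @param G_thr growth threshold, um (defaults to [growth_threshold()])
#' @param spacing step length, um
#' @return list with `tree` (grown [morph_tree()]) and `new_ids`
#' @export
grow_main_branch <- function(tree, volume, cut_ids, G_thr = NULL,
                             spacing = 1) {
  cut_ids <- as.integer(cut_ids)
  if (length(cut_ids) == 0) stop("cut_ids must be non-empty")
  root <- node_xyz(tree)[1, ]
  if (is.null(G_thr)) G_thr <- growth_threshold(volume, root)
  pts <- volume$points
  v_mean <- colMeans(pts)
  v_far <- pts[which.max(sqrt(colSums((t(pts) - root)^2))), ]
  q <- (v_mean + v_far) / 2
  u <- q - root
  if (sqrt(sum(u^2)) < 1e-9) u <- v_far - root
  u <- u / sqrt(sum(u^2))
  start_id <- cut_ids[which.max(tree$nodes$radius[cut_ids])]
  p0 <- node_xyz(tree)[start_id, ]
  n_steps <- floor(0.95 * G_thr / spacing)
  if (n_steps < 1) return(list(tree = tree, new_ids = integer(0)))
  steps <- sweep(outer(seq_len(n_steps) * spacing, u), 2, p0, "+")
  inside <- gv_contains(volume, steps)
  last <- if (all(inside)) n_steps else max(0L, which(!inside)[1] - 1L)
  if (last < 1) return(list(tree = tree, new_ids = integer(0)))
  n0 <- n_nodes(tree)
  add <- data.frame(id = n0 + seq_len(last), label = "apical",
                    x = steps[seq_len(last), 1], y = steps[seq_len(last), 2],
                    z = steps[seq_len(last), 3],
                    radius = tree$nodes$radius[start_id],
                    parent = c(start_id, n0 + seq_len(last - 1L)),
                    cut = FALSE)
  nodes <- rbind(tree$nodes, add)
  list(tree = morph_tree(nodes, provenance = tree$provenance),
       new_ids = n0 + seq_len(last))
}

## centred moving average with shrinking windows at the ends
.smooth_ma <- function(v, w) {
  n <- length(v)
  if (w <= 1 || n == 1) return(v)
  half <- floor(w / 2)
  cs <- cumsum(c(0, v))
  lo <- pmax(1, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Apply low-pass-filtered spatial jitter to newly grown nodes
#'
#' Imposes spatially autocorrelated noise on the coordinates of the grown
#' dendrite so it matches the roughness of biological cable: per branch run,
#' independent isotropic 3D Gaussian noise (sd = `amplitude`) is smoothed by
#' a centred moving average of `window` nodes along the path and added to the
#' new-node coordinates. Branch points and attachment junctions are pinned
#' (zero displacement) and the topology is unchanged.
#'
#' @param tree a [morph_tree()]
#' @param new_ids ids of the nodes to jitter (the grown material)
#' @param amplitude noise standard deviation, um (0 = identity)
#' @param window moving-average window, nodes
#' @param seed integer seed
#' @return the jittered [morph_tree()]
#' @export
jitter_new_nodes <- function(tree, new_ids, amplitude, window = 5L,
                             seed = 1L) {
  if (amplitude <= 0 || length(new_ids) == 0) return(tree)
  is_new <- logical(n_nodes(tree)); is_new[new_ids] <- TRUE
  cc <- .child_counts(tree)
  nd <- tree$nodes
  segs <- tree_segments(tree)
  .with_seed(seed, {
    for (seg in segs) {
      newin <- is_new[seg]
      if (!any(newin)) next
      run <- seg[newin]                       # contiguous tail of the segment
      end_pinned <- cc[seg[length(seg)]] >= 2L
      m <- length(run)
      if (m == 0 || (m == 1 && end_pinned)) next
      noise <- matrix(stats::rnorm(3 * m, sd = amplitude), m, 3)
      disp <- apply(noise, 2, .smooth_ma, w = window)
      disp <- matrix(disp, m, 3)
      ## pin the junction end (and, for internal runs, the far end)
      ramp <- if (end_pinned && m > 1)
        outer((m - seq_len(m)) / m, disp[1, ]) +
          outer((seq_len(m) - 1) / m, disp[m, ])
      else matrix(disp[1, ], m, 3, byrow = TRUE)
      disp <- disp - ramp
      if (end_pinned) disp[m, ] <- 0
      nd$x[run] <- nd$x[run] + disp[, 1]
      nd$y[run] <- nd$y[run] + disp[, 2]
      nd$z[run] <- nd$z[run] + disp[, 3]
    }
  })
  tree$nodes <- nd
  tree
}

#' Fit a quadratic diameter taper to a morphology
#'
#' Least-squares fit of `d(p) = scale * (1 - p/P)^2 + offset` over the
#' dendritic nodes of the input, where `p` is the path length of a node to
#' the root and `P` the maximal path length of the node's structure label
#' (basal and apical trees taper over their own extents). The diameter floor
#' `d_min` is the 5th percentile of the input's terminal diameters (toward
#' the very tips diameters level off to a constant, species-dependent value).
#'
#' @param tree a [morph_tree()]
#' @return list with `scale`, `offset`, `d_min` (all um)
#' @export
fit_taper <- function(tree) {
  nd <- tree$nodes
  dendritic <- which(!(nd$label %in% c("soma", "axon")) & nd$parent > 0)
  if (length(dendritic) < 3) {
    d0 <- 2 * stats::median(nd$radius)
    return(list(scale = 0, offset = d0, d_min = max(0.2, 0.5 * d0)))
  }
  pl <- .path_lengths(tree)
  pmax_lab <- tapply(pl[dendritic], nd$label[dendritic], max)
  P <- pmax(pmax_lab[nd$label[dendritic]], 1e-9)
  x <- pmax(0, 1 - pl[dendritic] / P)^2
  d <- 2 * nd$radius[dendritic]
  fit <- stats::lm.fit(cbind(1, x), d)
  offset <- fit$coefficients[1]; scale <- fit$coefficients[2]
  if (!is.finite(scale)) { scale <- 0; offset <- mean(d) }
  terms <- intersect(terminal_ids(tree), dendritic)
  d_min <- if (length(terms) > 0)
    as.numeric(stats::quantile(2 * nd$radius[terms], 0.05)) else
      max(0.2, 0.25 * offset)
  d_min <- max(d_min, 1e-3)
  list(scale = as.numeric(scale), offset = as.numeric(offset), d_min = d_min)
}

#' Apply a quadratic diameter taper to newly grown nodes
#'
#' Sets the diameter of every new node from the fitted quadratic
#' `d(p) = scale * (1 - p/P)^2 + offset` (with `P` the maximal path length
#' for the node's structure label in the repaired tree), floors diameters at
#' `d_min`, and enforces non-increasing diameters from each attachment point
#' toward the tips along the new material.
#'
#' @param tree a [morph_tree()]
#' @param new_ids ids of nodes to re-diameter
#' @param taper list with `scale`, `offset`, `d_min`; see [fit_taper()]
#' @return the tapered [morph_tree()]
#' @export
apply_taper <- function(tree, new_ids, taper) {
  if (length(new_ids) == 0) return(tree)
  nd <- tree$nodes
  pl <- .path_lengths(tree)
  dendritic <- which(!(nd$label %in% c("soma", "axon")))
  pmax_lab <- tapply(pl[dendritic], nd$label[dendritic], max)
  is_new <- logical(nrow(nd)); is_new[new_ids] <- TRUE
  new_ids <- sort(new_ids)
  P <- pmax(unname(pmax_lab[nd$label[new_ids]]), 1e-9)
  P[is.na(P)] <- max(pl)
  rad <- nd$radius
  rad[new_ids] <- pmax(taper$scale * pmax(0, 1 - pl[new_ids] / P)^2 +
                         taper$offset, taper$d_min) / 2
  par <- nd$parent
  for (i in new_ids)                       # cap below the (new) parent
    if (par[i] > 0 && is_new[par[i]]) rad[i] <- min(rad[i], rad[par[i]])
  nd$radius <- rad
  tree$nodes <- nd
  tree
}

#' Prune new material back to a target total length
#'
#' While the total cable length exceeds `target_total`, removes the shortest
#' terminal segment composed entirely of new nodes. Input nodes are never
#' removed; if the target lies below the input-only length the function
#' stops with a warning once no removable segment remains.
#'
#' @param tree a [morph_tree()]
#' @param new_ids ids of new (removable) nodes
#' @param target_total desired total cable length, um
#' @return list with `tree` and updated `new_ids`
#' @export
prune_to_length <- function(tree, new_ids, target_total) {
  is_new <- logical(n_nodes(tree)); is_new[new_ids] <- TRUE
  repeat {
    tot <- total_length(tree)
    if (tot <= target_total) break
    segs <- tree_segments(tree)
    cc <- .child_counts(tree)
    elen <- .edge_lengths(tree)
    cand <- Filter(function(s) cc[s[length(s)]] == 0L &&
                     all(is_new[s[-1]]), segs)
    if (length(cand) == 0) {
      warning("cannot prune to ", round(target_total, 1),
              " um without removing input nodes; stopping at ",
              round(tot, 1), " um")
      break
    }
    lens <- vapply(cand, function(s) sum(elen[s[-1]]), numeric(1))
    ## stop once removing even the shortest segment would overshoot by more
    ## than the current excess (we are within one segment of the target)
    if (min(lens) > 2 * (tot - target_total)) break
    drop_ids <- cand[[which.min(lens)]][-1]
    keep <- setdiff(seq_len(n_nodes(tree)), drop_ids)
    remap <- integer(n_nodes(tree)); remap[keep] <- seq_along(keep)
    nd <- tree$nodes[keep, , drop = FALSE]
    nd$id <- seq_len(nrow(nd))
    hp <- nd$parent > 0
    nd$parent[hp] <- remap[nd$parent[hp]]
    tree <- morph_tree(nd, provenance = tree$provenance)
    is_new <- is_new[keep]
  }
  list(tree = tree, new_ids = which(is_new))
}

## mean perpendicular deviation of interior nodes from the chord of their
## neighbours; a data-driven roughness scale for the jitter amplitude
.tortuosity_residual <- function(tree) {
  nd <- tree$nodes
  cc <- .child_counts(tree)
  xyz <- node_xyz(tree)
  dev <- c()
  for (i in which(cc == 1L & nd$parent > 0)) {
    child <- which(nd$parent == i)[1]
    a <- xyz[nd$parent[i], ]; b <- xyz[child, ]; p <- xyz[i, ]
    u <- b - a; nu <- sqrt(sum(u^2))
    if (nu < 1e-12) next
    t0 <- sum((p - a) * u) / nu^2
    dev <- c(dev, sqrt(sum((p - (a + t0 * u))^2)))
  }
  if (length(dev) == 0) 0 else mean(dev)
}

#' Repair a morphology by growing into a volume
#'
#' The central repair routine. Pipeline: resample the input to uniform node
#' spacing; estimate every unset growth parameter from the input neuron
#' (balancing factor from the root-angle distribution, quadratic taper and
#' jitter amplitude from the existing cable, growth threshold from the
#' volume chord, target-point count from branch-point density); optionally
#' grow a straight main branch; distribute target points in the volume by
#' density-weighted Monte Carlo sampling; grow new dendrite with the
#' optimal-wiring rule ([grow_mst()]), sprouting anywhere near the volume
#' (biological mode) or only from cut terminals (conserved mode); if a
#' desired branch-point count is given, iterate the growth by bisection on
#' the number of target points (at most 12 iterations, nested target
#' subsets, ties toward fewer points); finally jitter, taper and optionally
#' prune the new material.
#'
#' @param tree a [morph_tree()]: the incomplete input neuron.
#' @param volume a [growth_volume()]: where to grow.
#' @param params a [growth_params()]; `NULL` fields are estimated.
#' @param reference optional reference [morph_tree()]; when given, the
#'   branch-point count is matched to the reference's and the repaired tree
#'   is pruned to the reference's total length (unless `params` sets either
#'   explicitly).
#' @return an object of class `dendrite_repair`: list with `tree` (repaired
#'   [morph_tree()]), `new_ids`, `input` (the resampled input), `params`
#'   (all parameters as used, estimated values filled in), `stats_before`,
#'   `stats_after` ([branch_stats()] of input and repair), `unconnected`
#'   (count of unreachable targets) and `cut_ids`.
#' @seealso [random_cut()], [regeneration_percent()], [restoration_check()]
#' @export
fix_tree <- function(tree, volume, params = growth_params(),
                     reference = NULL) {
  stopifnot(inherits(tree, "morph_tree"), inherits(volume, "growth_volume"),
            inherits(params, "growth_params"))
  input <- resample_tree(tree, params$spacing)
  root <- node_xyz(input)[1, ]

  if (is.null(params$bf)) params$bf <- estimate_bf(input)
  if (is.null(params$taper)) params$taper <- fit_taper(input)
  g_thr_estimated <- is.null(params$G_thr)
  if (g_thr_estimated) params$G_thr <- growth_threshold(volume, root)
  if (is.null(params$npts)) params$npts <- estimate_target_count(input, volume)
  if (is.null(params$jitter_amplitude))
    params$jitter_amplitude <- 0.3 * .tortuosity_residual(input)
  if (!is.null(reference)) {
    if (is.null(params$target_nbr))
      params$target_nbr <- length(branch_point_ids(reference))
    if (is.null(params$prune_length))
      params$prune_length <- total_length(reference)
  }

  cut_ids <- find_cut_terminals(input, volume)
  work <- input
  main_ids <- integer(0)
  if (params$main_growth) {
    if (length(cut_ids) == 0) stop("main growth requires cut terminals")
    mg <- grow_main_branch(work, volume, cut_ids, G_thr = params$G_thr,
                           spacing = params$spacing)
    work <- mg$tree
    main_ids <- mg$new_ids
  }

  if (params$mode == "conserved" && length(cut_ids) == 0)
    stop("conserved growth requires cut-flagged terminals near the volume")
  node_vol_dist <- if (params$mode == "biological")
    gv_distance(volume, node_xyz(work)) else NULL

  dens_ids <- unique(c(branch_point_ids(input), terminal_ids(input)))
  dens_pts <- node_xyz(input)[dens_ids, , drop = FALSE]
  excl <- if (params$R_d > 0) node_xyz(input) else NULL
  n_max <- if (!is.null(params$target_nbr)) {
    ## the density estimate only sets the starting level; make sure the
    ## bisection range can actually cover the branch-point deficit
    deficit <- max(0L, params$target_nbr -
                     length(branch_point_ids(input)))
    4L * max(params$npts, 2L * deficit, 1L)
  } else params$npts
  targets <- distribute_targets(volume, n_max, density_points = dens_pts,
                                exclusion = excl, R_d = params$R_d,
                                seed = params$seed)

  run_growth <- function() {
  attach_ids <- if (params$mode == "conserved") c(cut_ids, main_ids) else
    unique(c(which(node_vol_dist <= params$G_thr), main_ids))
  if (length(attach_ids) == 0) return(NULL)
  grow_k <- function(k) grow_mst(work, targets[seq_len(k), , drop = FALSE],
                                 bf = params$bf, G_thr = params$G_thr,
                                 attach_ids = attach_ids)
  if (!is.null(params$target_nbr)) {
    ## bisection on the (nested) target count, then a local scan with the
    ## remaining budget: the branch-point count is only monotone in k on
    ## average, so neighbouring counts are worth probing
    target <- params$target_nbr
    lo <- 1L; hi <- n_max
    best <- NULL; best_err <- Inf; best_k <- NA_integer_
    seen <- integer(0)
    iter <- 0L
    eval_k <- function(k) {
      g <- grow_k(k)
      nbr <- length(branch_point_ids(g$tree))
      seen <<- c(seen, k)
      err <- abs(nbr - target)
      if (err < best_err || (err == best_err && k < best_k)) {
        best <<- g; best_err <<- err; best_k <<- k
      }
      nbr
    }
    while (iter < 8L && lo <= hi && best_err > 0) {
      iter <- iter + 1L
      k <- as.integer(floor((lo + hi) / 2))
      nbr <- eval_k(k)
      if (nbr < target) lo <- k + 1L else hi <- k - 1L
    }
    for (dk in c(-1L, 1L, -2L, 2L, -3L, 3L, -4L, 4L)) {
      if (iter >= 12L || best_err == 0) break
      k <- best_k + dk
      if (k < 1L || k > n_max || k %in% seen) next
      iter <- iter + 1L
      eval_k(k)
    }
    grown <- best
    params$npts <<- best_k
  } else {
    grown <- grow_k(min(params$npts, nrow(targets)))
  }
  grown
  }

  ## an estimated growth threshold can be degenerately small for thin sliver
  ## volumes; if it strands every target, relax it geometrically
  grown <- run_growth()
  attempts <- 0L
  while (g_thr_estimated && attempts < 6L &&
         (is.null(grown) || length(grown$new_ids) == 0)) {
    attempts <- attempts + 1L
    params$G_thr <- 2 * params$G_thr
    grown <- run_growth()
  }
  if (is.null(grown)) {
    warning("no part of the neuron is within G_thr of the growth volume; ",
            "returning the input unchanged")
    return(.repair_result(input, input, integer(0), params, 0L, cut_ids))
  }

  new_ids <- c(main_ids, grown$new_ids)
  if (length(new_ids) == 0) {
    warning("no target point was reachable; returning the input unchanged")
    return(.repair_result(input, input, integer(0), params,
                          length(grown$unconnected), cut_ids))
  }
  out <- grown$tree
  out <- jitter_new_nodes(out, new_ids, amplitude = params$jitter_amplitude,
                          window = params$jitter_window,
                          seed = params$seed + 1L)
  out <- apply_taper(out, new_ids, params$taper)
  if (!is.null(params$prune_length)) {
    pr <- prune_to_length(out, new_ids, params$prune_length)
    out <- pr$tree
    new_ids <- pr$new_ids
  }
  .repair_result(input, out, new_ids, params, length(grown$unconnected),
                 cut_ids)
}

.repair_result <- function(input, out, new_ids, params, unconnected,
                           cut_ids) {
  structure(list(tree = out, new_ids = as.integer(new_ids), input = input,
                 params = params,
                 stats_before = branch_stats(input),
                 stats_after = branch_stats(out),
                 unconnected = as.integer(unconnected),
                 cut_ids = as.integer(cut_ids)),
            class = "dendrite_repair")
}

#' @export
print.dendrite_repair <- function(x, ...) {
  cat(sprintf("<dendrite_repair> %s growth, bf = %.2f, G_thr = %.1f um\n",
              x$params$mode, x$params$bf, x$params$G_thr))
  cat(sprintf("  %d new nodes (%.1f um of new cable), %d unreachable targets\n",
              length(x$new_ids),
              total_length(x$tree) - total_length(x$input), x$unconnected))
  cat(sprintf("  branch points %d -> %d; total length %.1f -> %.1f um\n",
              x$stats_before$n_branch_points, x$stats_after$n_branch_points,
              x$stats_before$total_length, x$stats_after$total_length))
  invisible(x)
}

#' @export
summary.dendrite_repair <- function(object, ...) {
  print(object)
  cat("\nParameters as used:\n")
  print(object$params)
  invisible(object)
}

#' @export
coef.dendrite_repair <- function(object, ...) {
  p <- object$params
  c(bf = p$bf, G_thr = p$G_thr, npts = p$npts, R_d = p$R_d,
    jitter_amplitude = p$jitter_amplitude,
    taper_scale = p$taper$scale, taper_offset = p$taper$offset,
    taper_d_min = p$taper$d_min)
}

#' @export
plot.dendrite_repair <- function(x, ...) {
  plot(x$tree, new_ids = x$new_ids, ...)
  invisible(x)
}
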