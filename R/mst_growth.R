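#' Growth parameters for dendrite repair
#'
#' Collects every free parameter of the repair. Fields left `NULL` are
#' estimated from the input morphology by [fix_tree()]: the balancing factor
#' from the root-angle distribution, the growth threshold from the
#' growth-volume chord, the target-point count from branch-point density,
#' the taper from a quadratic fit to the input diameters, and the jitter
#' amplitude from the input's tortuosity.
#'
#' @param bf balancing factor in `[0, 1]`: 0 minimises total cable length,
#'   1 minimises path length to the soma.
#' @param G_thr growth threshold, um: the longest Euclidean span a single new
#'   connection may have (`Inf` = unbounded).
#' @param npts number of target points to distribute in the growth volume.
#' @param R_d margin, um: minimum distance of target points from every point
#'   of the existing (lesioned) neuron; avoids biasing regrowth toward
#'   regeneration or invasion.
#' @param mode `"biological"` (new dendrite may sprout from any part of the
#'   arbour near the growth volume) or `"conserved"` (growth restricted to
#'   cut-flagged incomplete terminals).
#' @param main_growth grow a straight main (apical-style) branch from the
#'   thickest cut terminal first, covering ~95% of the growth-volume chord.
#' @param target_nbr desired number of branch points of the repaired tree;
#'   reached by iterating the growth with more or fewer target points.
#' @param prune_length total dendritic length, um, to trim the repaired tree
#'   back to (only new material is ever removed).
#' @param jitter_amplitude standard deviation, um, of the low-pass-filtered
#'   spatial noise applied to new nodes (0 disables).
#' @param jitter_window moving-average window (node count) of the jitter's
#'   low-pass filter.
#' @param taper list with `scale`, `offset`, `d_min` (um) of the quadratic
#'   diameter taper applied to new material.
#' @param spacing resampling spacing, um, applied before growth.
#' @param seed integer seed making every stochastic stage reproducible.
#' @return an object of class `growth_params`
#' @export
growth_params <- function(bf = NULL, G_thr = NULL, npts = NULL, R_d = 0,
                          mode = c("biological", "conserved"),
                          main_growth = FALSE, target_nbr = NULL,
                          prune_length = NULL, jitter_amplitude = NULL,
                          jitter_window = 5L, taper = NULL, spacing = 1,
                          seed = 1L) {
  mode <- match.arg(mode)
  if (!is.null(bf) && (bf < 0 || bf > 1)) stop("bf must lie in [0, 1]")
  if (!is.null(G_thr) && G_thr <= 0) stop("G_thr must be positive")
  if (!is.null(npts) && npts < 0) stop("npts must be >= 0")
  if (R_d < 0) stop("R_d must be >= 0")
  if (spacing <= 0) stop("spacing must be positive")
  structure(list(bf = bf, G_thr = G_thr, npts = npts, R_d = R_d, mode = mode,
                 main_growth = isTRUE(main_growth), target_nbr = target_nbr,
                 prune_length = prune_length,
                 jitter_amplitude = jitter_amplitude,
                 jitter_window = as.integer(jitter_window), taper = taper,
                 spacing = spacing, seed = as.integer(seed)),
            class = "growth_params")
}

#' @export
print.growth_params <- function(x, ...) {
  fmt <- function(v) if (is.null(v)) "<estimate>" else
    paste(format(unlist(v), digits = 4), collapse = "/")
  cat("<growth_params>\n")
  for (f in c("bf", "G_thr", "npts", "R_d", "mode", "main_growth",
              "target_nbr", "prune_length", "jitter_amplitude",
              "jitter_window", "taper", "spacing", "seed"))
    cat(sprintf("  %-16s %s\n", f, fmt(x[[f]])))
  invisible(x)
}

#' Connection cost of attaching a target point to a tree node
#'
#' The optimal-wiring trade-off: `cost = d + bf * (PL(node) + d)` where `d`
#' is the Euclidean distance between target and node and `PL(node)` the path
#' length from the node to the root, so `PL(node) + d` is the path length the
#' new point would acquire. With `bf = 0` the cost reduces to the wiring
#' (cable) cost alone.
#'
#' @param target numeric 3-vector, um
#' @param node node id in `tree`
#' @param tree a [morph_tree()]
#' @param bf balancing factor in `[0, 1]`
#' @return the scalar cost
#' @export
connection_cost <- function(target, node, tree, bf) {
  d <- sqrt(sum((as.numeric(target) - node_xyz(tree)[node, ])^2))
  d + bf * (path_length(tree, node) + d)
}

#' Greedy optimal-wiring growth onto an existing tree
#'
#' Repeatedly connects the (unconnected target, attachable node) pair of
#' minimal [connection_cost()], subject to the Euclidean span not exceeding
#' `G_thr`. Each connected target becomes a new node (child of its chosen
#' attachment, inheriting its label and, as a placeholder, its radius) and is
#' itself attachable from then on. With `bf = 0` and unbounded `G_thr` this
#' greedy accretion is exactly Prim's algorithm, so the result is the
#' Euclidean minimum spanning tree over targets plus seed nodes.
#'
#' Ties in cost are broken lexicographically on (cost, node id, target
#' index), making the result deterministic across platforms.
#'
#' @param seed_tree a [morph_tree()] to grow from (left untouched in the
#'   output: its nodes keep id, position, radius and parent).
#' @param targets `m x 3` numeric matrix of target points, um.
#' @param bf balancing factor in `[0, 1]`.
#' @param G_thr growth threshold, um (`Inf` = unbounded).
#' @param attach_ids node ids of `seed_tree` that new dendrite may sprout
#'   from (`NULL` = all). Newly grown nodes are always attachable, which in
#'   conserved growth keeps all new material descending from the mask.
#' @return an object of class `mst_growth`: list with `tree` (the grown
#'   [morph_tree()]), `new_ids` (ids of appended nodes, in connection order),
#'   `order` (target row indices in connection order) and `unconnected`
#'   (target row indices that were never reachable).
#' @export
grow_mst <- function(seed_tree, targets, bf = 0.5, G_thr = Inf,
                     attach_ids = NULL) {
  stopifnot(inherits(seed_tree, "morph_tree"))
  targets <- as.matrix(targets)
  if (ncol(targets) == 2) targets <- cbind(targets, 0)
  if (nrow(targets) > 0 && ncol(targets) != 3)
    stop("targets must be an m x 3 matrix")
  if (bf < 0 || bf > 1) stop("bf must lie in [0, 1]")
  if (is.null(attach_ids)) attach_ids <- seq_len(n_nodes(seed_tree))
  attach_ids <- as.integer(attach_ids)
  if (length(attach_ids) == 0) stop("attach_ids must be non-empty")
  n0 <- n_nodes(seed_tree)
  m <- nrow(targets)
  nd <- seed_tree$nodes

  ntot <- n0 + m
  x <- c(nd$x, numeric(m)); y <- c(nd$y, numeric(m)); z <- c(nd$z, numeric(m))
  rad <- c(nd$radius, numeric(m)); par <- c(nd$parent, integer(m))
  lab <- c(nd$label, character(m)); cutf <- c(nd$cut, logical(m))
  pl <- c(.path_lengths(seed_tree), numeric(m))

  cost_to <- function(node, tx, ty, tz) {
    d <- sqrt((x[node] - tx)^2 + (y[node] - ty)^2 + (z[node] - tz)^2)
    cost <- d + bf * (pl[node] + d)
    cost[d > G_thr] <- Inf
    cost
  }

  best_cost <- rep(Inf, m); best_node <- rep(NA_integer_, m)
  for (t in seq_len(m)) {
    cs <- cost_to(attach_ids, targets[t, 1], targets[t, 2], targets[t, 3])
    if (length(cs) > 0 && min(cs) < Inf) {
      j <- which(cs == min(cs))
      best_node[t] <- min(attach_ids[j])        # node-id tie-break
      best_cost[t] <- min(cs)
    }
  }

  connected <- logical(m)
  ord <- integer(0)
  nxt <- n0
  repeat {
    open <- which(!connected & is.finite(best_cost))
    if (length(open) == 0) break
    cmin <- min(best_cost[open])
    cand <- open[best_cost[open] <= cmin]
    if (length(cand) > 1) {                     # lexicographic tie-break
      cand <- cand[best_node[cand] == min(best_node[cand])]
      cand <- cand[1]
    }
    t <- cand
    node <- best_node[t]
    nxt <- nxt + 1L
    d <- sqrt((x[node] - targets[t, 1])^2 + (y[node] - targets[t, 2])^2 +
                (z[node] - targets[t, 3])^2)
    x[nxt] <- targets[t, 1]; y[nxt] <- targets[t, 2]; z[nxt] <- targets[t, 3]
    rad[nxt] <- rad[node]; par[nxt] <- node
    lab[nxt] <- if (lab[node] == "soma") "basal" else lab[node]
    cutf[nxt] <- FALSE
    pl[nxt] <- pl[node] + d
    connected[t] <- TRUE
    ord <- c(ord, t)
    rest <- which(!connected)
    if (length(rest) > 0) {
      csn <- cost_to(rep(nxt, length(rest)), targets[rest, 1],
                     targets[rest, 2], targets[rest, 3])
      upd <- csn < best_cost[rest]
      best_cost[rest[upd]] <- csn[upd]
      best_node[rest[upd]] <- nxt
    }
  }

  k <- nxt - n0
  nodes <- data.frame(id = seq_len(n0 + k),
                      label = lab[seq_len(n0 + k)],
                      x = x[seq_len(n0 + k)], y = y[seq_len(n0 + k)],
                      z = z[seq_len(n0 + k)], radius = rad[seq_len(n0 + k)],
                      parent = par[seq_len(n0 + k)], cut = cutf[seq_len(n0 + k)])
  out <- list(tree = morph_tree(nodes, provenance = seed_tree$provenance),
              new_ids = if (k > 0) (n0 + 1L):(n0 + k) else integer(0),
              order = ord,
              unconnected = which(!connected))
  class(out) <- "mst_growth"
  out
}

#' @export
print.mst_growth <- function(x, ...) {
  cat(sprintf("<mst_growth> %d targets connected, %d unreachable; tree now %d nodes\n",
              length(x$order), length(x$unconnected), n_nodes(x$tree)))
  invisible(x)
}

#' Connection order of a growth result
#'
#' The accretion sequence of [grow_mst()]: target row indices in the order
#' they were connected. Replaying this order (each new node attached to a
#' node that already existed) reproduces the grown tree.
#'
#' @param result an `mst_growth` object from [grow_mst()]
#' @return integer vector of target indices
#' @export
growth_order <- function(result) {
  stopifnot(inherits(result, "mst_growth"))
  result$order
}

## evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
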