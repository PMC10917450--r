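#' Rooted neuronal morphology tree
#'
#' `morph_tree` is the universal morphology container of the package: a rooted,
#' labelled tree of 3D nodes with radii, backed one-to-one by the 7-column SWC
#' format. Nodes are stored in parent-before-child order and node ids always
#' equal their storage position (1..N); the single root has `parent == -1`.
#'
#' @param nodes data frame with columns `id` (integer), `label` (one of
#'   `"soma"`, `"axon"`, `"basal"`, `"apical"`, `"custom"`), `x`, `y`, `z`
#'   (positions, micrometres), `radius` (micrometres, strictly positive) and
#'   `parent` (id of the parent node, `-1` for the root). An optional logical
#'   column `cut` marks terminals known to be incomplete (cut ends).
#' @param provenance free-text metadata kept with the tree (file of origin,
#'   generator settings, ...).
#'
#' @return An object of class `morph_tree`: a list with elements `nodes`
#'   (normalised data frame as above, ids renumbered 1..N in
#'   parent-before-child order) and `provenance`.
#'
#' @details Input node ids may be arbitrary; they are renumbered so that
#'   every parent precedes its children. Construction fails if the node set
#'   has no root, several roots, dangling parent references, duplicated ids
#'   or non-positive radii.
#'
#' @seealso [read_swc()], [write_swc()], [resample_tree()], [delete_subtree()]
#' @export
morph_tree <- function(nodes, provenance = "") {
  stopifnot(is.data.frame(nodes))
  req <- c("id", "label", "x", "y", "z", "radius", "parent")
  miss <- setdiff(req, names(nodes))
  if (length(miss) > 0)
    stop("missing node columns: ", paste(miss, collapse = ", "))
  if (nrow(nodes) == 0) stop("a morphology must contain at least one node")
  if (!"cut" %in% names(nodes)) nodes$cut <- FALSE
  nodes$id <- as.integer(nodes$id)
  nodes$parent <- as.integer(nodes$parent)
  nodes$label <- as.character(nodes$label)
  nodes$cut <- as.logical(nodes$cut)
  bad_lab <- setdiff(unique(nodes$label), .swc_labels)
  if (length(bad_lab) > 0)
    stop("unknown structure labels: ", paste(bad_lab, collapse = ", "))
  if (anyDuplicated(nodes$id))
    stop("duplicate node ids: ",
         paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "))
  if (any(!is.finite(nodes$radius)) || any(nodes$radius <= 0))
    stop("all radii must be finite and > 0")
  if (any(!is.finite(as.matrix(nodes[, c("x", "y", "z")]))))
    stop("node coordinates must be finite")

  roots <- nodes$id[nodes$parent == -1L]
  if (length(roots) == 0) stop("no root node (parent == -1) found")
  if (length(roots) > 1)
    stop("multiple roots found (ids ", paste(roots, collapse = ", "),
         "); multi-root files are not supported")
  known <- c(-1L, nodes$id)
  dangle <- nodes$id[!(nodes$parent %in% known)]
  if (length(dangle) > 0)
    stop("dangling parent reference at node(s) ",
         paste(dangle, collapse = ", "))

  n <- nrow(nodes)
  ## rows already in parent-before-child order? renumber in place, keeping
  ## the storage order (so positions of surviving rows are predictable)
  pos <- match(nodes$parent, nodes$id)
  if (all(is.na(pos) | pos < seq_len(n)) && sum(is.na(pos)) == 1 &&
      is.na(pos[1])) {
    nodes$parent <- ifelse(is.na(pos), -1L, pos)  # new id = row position
    nodes$id <- seq_len(n)
    rownames(nodes) <- NULL
    return(structure(list(nodes = nodes, provenance = provenance),
                     class = "morph_tree"))
  }
  ## otherwise: topological renumbering, breadth-first from the root
  idx_of <- match(nodes$parent, nodes$id)        # NA for root
  kids <- split(seq_len(n), factor(idx_of, levels = seq_len(n)))
  order_idx <- integer(n)
  order_idx[1] <- which(nodes$parent == -1L)
  head <- 1L; tail <- 1L
  while (head <= tail) {
    ch <- kids[[order_idx[head]]]
    if (length(ch) > 0) {
      order_idx[(tail + 1L):(tail + length(ch))] <- ch
      tail <- tail + length(ch)
    }
    head <- head + 1L
  }
  if (tail < n) {
    orphan <- setdiff(seq_len(n), order_idx[seq_len(tail)])
    stop("disconnected nodes (unreachable from root): ",
         paste(nodes$id[orphan], collapse = ", "))
  }
  nodes <- nodes[order_idx, , drop = FALSE]
  remap <- integer(max(nodes$id))
  remap[nodes$id] <- seq_len(n)
  has_par <- nodes$parent != -1L
  nodes$parent[has_par] <- remap[nodes$parent[has_par]]
  nodes$id <- seq_len(n)
  rownames(nodes) <- NULL

  structure(list(nodes = nodes, provenance = provenance),
            class = "morph_tree")
}

.swc_labels <- c("soma", "axon", "basal", "apical", "custom")
.swc_codes <- c(soma = 1L, axon = 2L, basal = 3L, apical = 4L, custom = 5L)

#' @export
print.morph_tree <- function(x, ...) {
  nd <- x$nodes
  cat(sprintf("<morph_tree> %d nodes, %d branch points, %d terminals\n",
              nrow(nd), length(branch_point_ids(x)), length(terminal_ids(x))))
  cat(sprintf("  total cable length %.2f um; labels: %s\n",
              total_length(x),
              paste(names(table(nd$label)), collapse = ", ")))
  if (any(nd$cut))
    cat("  cut-flagged terminals:", paste(which(nd$cut), collapse = ", "), "\n")
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' @export
summary.morph_tree <- function(object, ...) {
  s <- branch_stats(object)
  print(object)
  cat(sprintf("  mean segment length %.2f um over %d segments\n",
              s$mean_segment_length, s$n_segments))
  invisible(s)
}

#' @export
plot.morph_tree <- function(x, new_ids = integer(0), plane = c("xy", "xz"), ...) {
  plane <- match.arg(plane)
  nd <- x$nodes
  cols <- if (plane == "xy") c("x", "y") else c("x", "z")
  graphics::plot(nd[[cols[1]]], nd[[cols[2]]], type = "n", asp = 1,
                 xlab = paste0(cols[1], " (um)"), ylab = paste0(cols[2], " (um)"), ...)
  has_par <- nd$parent > 0
  seg_col <- ifelse(seq_len(nrow(nd)) %in% new_ids, "forestgreen", "grey25")
  graphics::segments(nd[[cols[1]]][nd$parent[has_par]],
                     nd[[cols[2]]][nd$parent[has_par]],
                     nd[[cols[1]]][has_par], nd[[cols[2]]][has_par],
                     col = seg_col[has_par])
  graphics::points(nd[[cols[1]]][1], nd[[cols[2]]][1], pch = 16, col = "red")
  invisible(x)
}

#' Number of nodes in a morphology
#' @param tree a [morph_tree()]
#' @return integer count
#' @export
n_nodes <- function(tree) nrow(tree$nodes)

#' Node coordinates as a numeric matrix
#' @param tree a [morph_tree()]
#' @return N x 3 matrix of x, y, z in micrometres
#' @export
node_xyz <- function(tree) {
  as.matrix(tree$nodes[, c("x", "y", "z")])
}

## Euclidean length of every parent->child edge; the root gets 0.
.edge_lengths <- function(tree) {
  nd <- tree$nodes
  xyz <- node_xyz(tree)
  len <- numeric(nrow(nd))
  has_par <- nd$parent > 0
  d <- xyz[has_par, , drop = FALSE] - xyz[nd$parent[has_par], , drop = FALSE]
  len[has_par] <- sqrt(rowSums(d * d))
  len
}

#' Total cable length of a morphology
#' @param tree a [morph_tree()]
#' @return total length in micrometres (sum of all parent-child edges)
#' @export
total_length <- function(tree) sum(.edge_lengths(tree))

#' Path length from a node to the root
#'
#' Sum of Euclidean parent-child edge lengths along the unique path from
#' `node` up to the root. The root has path length 0.
#'
#' @param tree a [morph_tree()]
#' @param node node id (integer); if missing, path lengths of all nodes are
#'   returned as a vector.
#' @return length in micrometres (scalar, or vector over all nodes)
#' @export
path_length <- function(tree, node) {
  pl <- .path_lengths(tree)
  if (missing(node)) return(pl)
  node <- as.integer(node)
  if (any(node < 1L | node > n_nodes(tree)))
    stop("unknown node id: ", paste(node[node < 1L | node > n_nodes(tree)],
                                    collapse = ", "))
  pl[node]
}

.path_lengths <- function(tree) {
  nd <- tree$nodes
  len <- .edge_lengths(tree)
  pl <- numeric(nrow(nd))
  for (i in seq_len(nrow(nd))) {
    p <- nd$parent[i]
    pl[i] <- if (p > 0) pl[p] + len[i] else 0
  }
  pl
}

## number of children of each node
.child_counts <- function(tree) {
  nd <- tree$nodes
  tabulate(nd$parent[nd$parent > 0], nbins = nrow(nd))
}

#' Branch point ids (nodes with two or more children)
#' @param tree a [morph_tree()]
#' @return integer vector of node ids
#' @export
branch_point_ids <- function(tree) which(.child_counts(tree) >= 2L)

#' Terminal (leaf) node ids
#' @param tree a [morph_tree()]
#' @return integer vector of node ids
#' @export
terminal_ids <- function(tree) {
  ids <- which(.child_counts(tree) == 0L)
  setdiff(ids, 1L)  # a root-only tree has no terminals in the dendritic sense
}

#' All descendants of a node (including the node itself)
#' @param tree a [morph_tree()]
#' @param node node id
#' @return integer vector of node ids, in storage order
#' @export
subtree_ids <- function(tree, node) {
  node <- as.integer(node)
  if (node < 1L || node > n_nodes(tree)) stop("unknown node id: ", node)
  n <- n_nodes(tree)
  inset <- logical(n)
  inset[node] <- TRUE
  par <- tree$nodes$parent
  if (node < n) for (i in (node + 1L):n) {
    if (par[i] > 0 && inset[par[i]]) inset[i] <- TRUE
  }
  which(inset)
}

#' Sever a subtree from a morphology
#'
#' Removes the subtree rooted at `node` and returns both parts. The remaining
#' tree keeps the parent of `node`; the severed part is re-rooted at `node`.
#' Node counts are conserved exactly; cable lengths of the two parts sum to
#' the original total minus the single stem edge that joined them (which
#' belongs to neither part once severed).
#'
#' @param tree a [morph_tree()]
#' @param node id of the subtree root to sever; must not be the tree root.
#' @return list with elements `remaining` and `severed`, both [morph_tree()]s.
#' @export
delete_subtree <- function(tree, node) {
  node <- as.integer(node)
  if (node == 1L) stop("cannot sever the tree at its root")
  sub <- subtree_ids(tree, node)
  nd <- tree$nodes
  sev <- nd[sub, , drop = FALSE]
  sev$parent[sev$id == node] <- -1L
  rem <- nd[-sub, , drop = FALSE]
  list(remaining = morph_tree(rem, provenance = tree$provenance),
       severed = morph_tree(sev, provenance = paste0(tree$provenance,
                                                     " [severed at ", node, "]")))
}

#' Decompose a morphology into segments
#'
#' A segment runs from one topological point (root, branch point) to the next
#' topological point (branch point or termination). Interior nodes of a
#' segment have exactly one child.
#'
#' @param tree a [morph_tree()]
#' @return list of integer vectors; each vector holds the node ids of one
#'   segment in root-to-tip order, starting at the parent topological point.
#' @export
tree_segments <- function(tree) {
  nd <- tree$nodes
  cc <- .child_counts(tree)
  n <- nrow(nd)
  if (n == 1L) return(list())
  topo <- cc >= 2L | seq_len(n) == 1L           # segment start points
  ends <- which(cc == 0L | (cc >= 2L & seq_len(n) != 1L))
  ends <- setdiff(ends, 1L)
  lapply(ends, function(e) {
    path <- e
    i <- nd$parent[e]
    while (i > 0 && !topo[i]) {
      path <- c(i, path)
      i <- nd$parent[i]
    }
    c(i, path)
  })
}

#' Resample a morphology to a uniform node spacing
#'
#' Subdivides every parent-child edge longer than `spacing` into equal pieces
#' so that consecutive nodes are at most `spacing` apart, without changing the
#' piecewise-linear course of the cable. Branch points and terminations are
#' preserved exactly; radii are interpolated linearly along each edge. Runs of
#' interior nodes that are collinear with their neighbours are merged before
#' subdivision. The growth rule assumes dense uniform node spacing for its
#' attachment candidates, so repairs resample to 1 um by default.
#'
#' @param tree a [morph_tree()]
#' @param spacing maximum distance between neighbouring nodes, micrometres.
#' @return a resampled [morph_tree()]
#' @export
resample_tree <- function(tree, spacing = 1) {
  if (!is.numeric(spacing) || length(spacing) != 1 || spacing <= 0)
    stop("spacing must be a single positive number")
  if (all(.edge_lengths(tree) <= spacing * (1 + 1e-9)))
    return(tree)                    # already conforming; nothing to subdivide
  nd <- tree$nodes
  segs <- tree_segments(tree)
  keep <- nd[1, , drop = FALSE]          # root row
  out <- list(keep)
  next_id <- 1L
  new_id_of <- integer(nrow(nd)); new_id_of[1] <- 1L
  for (seg in segs) {
    P <- as.matrix(nd[seg, c("x", "y", "z")])
    R <- nd$radius[seg]
    ## drop interior vertices collinear with their neighbours
    m <- length(seg)
    if (m > 2) {
      keep_v <- rep(TRUE, m)
      for (j in 2:(m - 1)) {
        a <- P[j, ] - P[j - 1, ]; b <- P[j + 1, ] - P[j, ]
        na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
        if (na < 1e-12 || nb < 1e-12) next
        cr <- c(a[2] * b[3] - a[3] * b[2],
                a[3] * b[1] - a[1] * b[3],
                a[1] * b[2] - a[2] * b[1])
        if (sqrt(sum(cr^2)) / (na * nb) < 1e-9) keep_v[j] <- FALSE
      }
      ## collapse collinear runs, re-interpolating radii over the straight run
      P <- P[keep_v, , drop = FALSE]; R <- R[keep_v]
      seg_kept <- seg[keep_v]
    } else seg_kept <- seg
    prev_new <- new_id_of[seg[1]]
    for (j in 2:nrow(P)) {
      d <- sqrt(sum((P[j, ] - P[j - 1, ])^2))
      nsub <- max(1L, ceiling(d / spacing))
      for (k in seq_len(nsub)) {
        t <- k / nsub
        row <- nd[seg_kept[j], , drop = FALSE]
        row$x <- P[j - 1, 1] + t * (P[j, 1] - P[j - 1, 1])
        row$y <- P[j - 1, 2] + t * (P[j, 2] - P[j - 1, 2])
        row$z <- P[j - 1, 3] + t * (P[j, 3] - P[j - 1, 3])
        row$radius <- R[j - 1] + t * (R[j] - R[j - 1])
        row$cut <- if (k == nsub && j == nrow(P)) nd$cut[seg[length(seg)]] else FALSE
        next_id <- next_id + 1L
        row$id <- next_id
        row$parent <- prev_new
        out[[length(out) + 1L]] <- row
        prev_new <- next_id
      }
      new_id_of[seg_kept[j]] <- prev_new
    }
  }
  nodes <- do.call(rbind, out)
  morph_tree(nodes, provenance = tree$provenance)
}
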