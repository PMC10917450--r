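#' Branch statistics of a morphology
#'
#' Segments are delimited by topological points: a segment runs from a branch
#' point (or the root) to the next branch point or termination. Diameters are
#' twice the stored radii.
#'
#' @param tree a [morph_tree()]
#' @return an object of class `morpho_stats`: list with `n_branch_points`,
#'   `n_terminals`, `n_segments`, `total_length` (um), `mean_segment_length`
#'   (um), `mean_segment_diameter` (um), and per-label data frame `per_label`
#'   (mean segment length and diameter for each structure label present).
#' @export
branch_stats <- function(tree) {
  stopifnot(inherits(tree, "morph_tree"))
  segs <- tree_segments(tree)
  elen <- .edge_lengths(tree)
  nd <- tree$nodes
  seg_len <- vapply(segs, function(s) sum(elen[s[-1]]), numeric(1))
  seg_diam <- vapply(segs, function(s) mean(2 * nd$radius[s]), numeric(1))
  seg_lab <- vapply(segs, function(s) nd$label[s[length(s)]], character(1))
  per_label <- if (length(segs) > 0) {
    do.call(rbind, lapply(split(seq_along(segs), seg_lab), function(i)
      data.frame(label = seg_lab[i[1]],
                 n_segments = length(i),
                 mean_segment_length = mean(seg_len[i]),
                 mean_segment_diameter = mean(seg_diam[i]))))
  } else data.frame(label = character(0), n_segments = integer(0),
                    mean_segment_length = numeric(0),
                    mean_segment_diameter = numeric(0))
  rownames(per_label) <- NULL
  structure(list(
    n_branch_points = length(branch_point_ids(tree)),
    n_terminals = length(terminal_ids(tree)),
    n_segments = length(segs),
    total_length = sum(elen),
    mean_segment_length = if (length(segs) > 0) mean(seg_len) else 0,
    mean_segment_diameter = if (length(segs) > 0) mean(seg_diam) else 0,
    per_label = per_label), class = "morpho_stats")
}

#' @export
print.morpho_stats <- function(x, ...) {
  cat(sprintf(paste0("<morpho_stats> NBr = %d, terminals = %d, total length ",
                     "%.1f um,\n  mean segment length %.2f um over %d segments\n"),
              x$n_branch_points, x$n_terminals, x$total_length,
              x$mean_segment_length, x$n_segments))
  invisible(x)
}

#' @export
as.data.frame.morpho_stats <- function(x, ...) {
  data.frame(n_branch_points = x$n_branch_points,
             n_terminals = x$n_terminals, n_segments = x$n_segments,
             total_length = x$total_length,
             mean_segment_length = x$mean_segment_length,
             mean_segment_diameter = x$mean_segment_diameter)
}

#' Sholl analysis
#'
#' Counts crossings of concentric spheres centred on the root. Each
#' parent-child edge contributes one crossing of every sphere whose radius
#' lies strictly between the smaller and up to (inclusive) the larger of the
#' two node-to-root Euclidean distances.
#'
#' @param tree a [morph_tree()]
#' @param step sphere spacing in micrometres (default 10); radii run
#'   `step, 2*step, ...` up to the largest node distance.
#' @return list with numeric vectors `radii` and `counts`
#' @export
sholl <- function(tree, step = 10) {
  if (!is.numeric(step) || length(step) != 1 || step <= 0)
    stop("step must be a single positive number")
  nd <- tree$nodes
  xyz <- node_xyz(tree)
  r0 <- xyz[1, ]
  dist <- sqrt(colSums((t(xyz) - r0)^2))
  rmax <- max(dist)
  if (rmax < step) return(list(radii = numeric(0), counts = numeric(0)))
  radii <- step * seq_len(floor(rmax / step + 1e-9))
  has_par <- nd$parent > 0
  d1 <- dist[nd$parent[has_par]]
  d2 <- dist[has_par]
  lo <- pmin(d1, d2); hi <- pmax(d1, d2)
  counts <- vapply(radii, function(r) sum(lo < r & hi >= r), numeric(1))
  list(radii = radii, counts = counts)
}

#' L1 distance between Sholl profiles on a common grid
#'
#' Both profiles are evaluated at radii `step, 2*step, ...` up to the larger
#' of the two maximal extents; absent shells count as zero crossings.
#'
#' @param tree_a,tree_b [morph_tree()]s
#' @param step sphere spacing, micrometres
#' @return sum of absolute count differences
#' @export
sholl_l1 <- function(tree_a, tree_b, step = 10) {
  sa <- sholl(tree_a, step); sb <- sholl(tree_b, step)
  n <- max(length(sa$counts), length(sb$counts))
  pad <- function(v) c(v, rep(0, n - length(v)))
  sum(abs(pad(sa$counts) - pad(sb$counts)))
}

#' Root-angle distribution of a morphology
#'
#' For every non-root node, the angle between the local growth direction
#' (parent to node) and the direction pointing away from the root at that
#' node. Perfectly radial (sunburst) growth gives angles of 0; the
#' distribution tightens toward 0 as the balancing factor of the growth rule
#' increases, which is what [estimate_bf()] exploits.
#'
#' @param tree a [morph_tree()], ideally resampled to uniform spacing so each
#'   local direction carries equal weight.
#' @return numeric vector of angles in radians, in `[0, pi]`, one per
#'   non-root node (nodes with a degenerate direction are dropped).
#' @export
root_angle_distribution <- function(tree) {
  nd <- tree$nodes
  xyz <- node_xyz(tree)
  r0 <- xyz[1, ]
  has_par <- which(nd$parent > 0)
  e <- xyz[has_par, , drop = FALSE] - xyz[nd$parent[has_par], , drop = FALSE]
  a <- t(t(xyz[has_par, , drop = FALSE]) - r0)      # away-from-root direction
  ne <- sqrt(rowSums(e * e)); na <- sqrt(rowSums(a * a))
  ok <- ne > 1e-12 & na > 1e-12
  cosang <- rowSums(e[ok, , drop = FALSE] * a[ok, , drop = FALSE]) /
    (ne[ok] * na[ok])
  acos(pmin(1, pmax(-1, cosang)))
}

#' Root-mean-square error as a percentage of a reference value
#'
#' `100 * sqrt(mean((values - reference)^2)) / reference`, the deviation
#' measure used to compare repaired and cut morphologies against a reference.
#'
#' @param values numeric vector of measurements
#' @param reference scalar reference value (non-zero)
#' @return RMSE as a percentage of `reference`
#' @export
rmse_percent <- function(values, reference) {
  if (!is.numeric(reference) || length(reference) != 1 || reference == 0)
    stop("reference must be a single non-zero number")
  100 * sqrt(mean((values - reference)^2)) / abs(reference)
}

#' Discrete Frechet distance between two curves
#'
#' Standard dynamic-programming computation over all monotone couplings of
#' the two point sequences; symmetric, and never smaller than the distance
#' between either pair of matched endpoints.
#'
#' @param P,Q numeric matrices (rows = points) or numeric vectors (treated as
#'   1D curves); both non-empty, same number of columns.
#' @return the discrete Frechet distance
#' @export
discrete_frechet <- function(P, Q) {
  if (is.vector(P)) P <- matrix(P, ncol = 1)
  if (is.vector(Q)) Q <- matrix(Q, ncol = 1)
  if (nrow(P) == 0 || nrow(Q) == 0) stop("both curves must be non-empty")
  if (ncol(P) != ncol(Q)) stop("curves must live in the same dimension")
  n <- nrow(P); m <- nrow(Q)
  D <- matrix(0, n, m)
  for (j in seq_len(m))
    D[, j] <- sqrt(rowSums((P - matrix(Q[j, ], n, ncol(P), byrow = TRUE))^2))
  ca <- matrix(0, n, m)
  ca[1, 1] <- D[1, 1]
  for (i in 2:max(n, 2)) if (n > 1) ca[i, 1] <- max(ca[i - 1, 1], D[i, 1])
  for (j in 2:max(m, 2)) if (m > 1) ca[1, j] <- max(ca[1, j - 1], D[1, j])
  if (n > 1 && m > 1) for (i in 2:n) for (j in 2:m)
    ca[i, j] <- max(min(ca[i - 1, j], ca[i - 1, j - 1], ca[i, j - 1]), D[i, j])
  ca[n, m]
}
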