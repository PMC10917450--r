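#' Growth volume: a bounded 2D/3D region for dendritic regrowth
#'
#' Builds a watertight boundary around a set of defining points as an
#' alpha-complex of their Delaunay triangulation. `alpha = 0` keeps every
#' Delaunay simplex and therefore equals the convex hull; `alpha = 1` is the
#' tightest boundary that still contains every defining point; intermediate
#' values interpolate on the critical-radius scale of the complex, so the
#' enclosed measure is non-increasing in `alpha`.
#'
#' Point sets whose extent normal to their best plane is negligible are
#' treated as 2D (class IV da neurons of Drosophila larvae, for instance,
#' arborise in an essentially flat plane); containment then ignores the
#' out-of-plane coordinate.
#'
#' @param points numeric matrix of defining points: `n x 3` (or `n x 2`,
#'   taken as z = 0). At least 3 non-collinear (2D) or 4 non-coplanar (3D)
#'   points are required.
#' @param alpha tightness in `[0, 1]`; 0 = convex hull (default).
#' @return an object of class `growth_volume` with elements `points`
#'   (defining points, always `n x 3`), `is2d`, `simplices`, `kept` (logical
#'   mask of simplices in the alpha complex), `measure` (area in um^2 for 2D,
#'   volume in um^3 for 3D) and `alpha`.
#' @seealso [gv_contains()], [gv_measure()], [gv_chord_length()],
#'   [growth_threshold()]
#' @export
growth_volume <- function(points, alpha = 0) {
  points <- as.matrix(points)
  if (ncol(points) == 2) points <- cbind(points, 0)
  if (ncol(points) != 3) stop("points must have 2 or 3 columns")
  storage.mode(points) <- "double"
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha < 0 || alpha > 1)
    stop("alpha must be a single number in [0, 1]")
  if (nrow(points) < 3) stop("degenerate point set: need at least 3 points")

  extent <- apply(points, 2, function(v) diff(range(v)))
  tol2d <- 1e-6 * max(extent, 1)
  is2d <- extent[3] <= tol2d
  z0 <- mean(points[, 3])
  pts <- if (is2d) points[, 1:2, drop = FALSE] else points
  pts_u <- unique(round(pts, 9))
  if ((is2d && nrow(pts_u) < 3) || (!is2d && nrow(pts_u) < 4))
    stop("degenerate point set: too few distinct points for a ",
         if (is2d) "2D" else "3D", " volume")

  idx <- if (is2d) .delaunay_2d(pts) else .delaunay_3d(pts)
  radii <- .circumradii(pts, idx)
  meas <- .simplex_measures(pts, idx)
  ok <- is.finite(radii) & meas > 1e-12 * max(meas)
  idx <- idx[ok, , drop = FALSE]; radii <- radii[ok]; meas <- meas[ok]
  if (nrow(idx) == 0) stop("degenerate point set: all simplices are flat")

  ## critical radius: smallest threshold at which every defining point is
  ## still a vertex of some kept simplex
  r_pt <- rep(Inf, nrow(pts))
  for (k in seq_len(nrow(idx)))
    r_pt[idx[k, ]] <- pmin(r_pt[idx[k, ]], radii[k])
  used <- sort(unique(as.vector(idx)))
  r_crit <- max(r_pt[used])
  r_max <- max(radii)
  r_thr <- r_crit + (1 - alpha) * (r_max - r_crit)
  kept <- radii <= r_thr * (1 + 1e-12)

  ## fast containment path: with the full complex kept, a 2D volume is the
  ## convex hull of its defining points, a plain polygon test
  hull2d <- if (is2d && all(kept)) {
    h <- grDevices::chull(pts[, 1], pts[, 2])
    pts[c(h, h[1]), , drop = FALSE]
  } else NULL

  structure(list(points = points, is2d = is2d, z0 = z0,
                 simplices = idx, radii = radii, simplex_measures = meas,
                 kept = kept, measure = sum(meas[kept]), alpha = alpha,
                 hull2d = hull2d),
            class = "growth_volume")
}

#' @export
print.growth_volume <- function(x, ...) {
  cat(sprintf("<growth_volume> %s, %d defining points, alpha = %.2f\n",
              if (x$is2d) "2D" else "3D", nrow(x$points), x$alpha))
  cat(sprintf("  enclosed %s: %.2f um^%d; %d of %d simplices kept\n",
              if (x$is2d) "area" else "volume", x$measure,
              if (x$is2d) 2L else 3L, sum(x$kept), length(x$kept)))
  invisible(x)
}

.gv_pts <- function(vol, q) {
  q <- as.matrix(q)
  if (ncol(q) == 2) q <- cbind(q, vol$z0)
  if (vol$is2d) q[, 1:2, drop = FALSE] else q
}

.gv_def <- function(vol) {
  if (vol$is2d) vol$points[, 1:2, drop = FALSE] else vol$points
}

#' Containment test for a growth volume
#'
#' @param vol a [growth_volume()]
#' @param q query points, `m x 3` matrix (or `m x 2`); for 2D volumes the
#'   out-of-plane coordinate is ignored.
#' @return logical vector of length `m`
#' @export
gv_contains <- function(vol, q) {
  q <- .gv_pts(vol, q)
  if (!is.null(vol$hull2d))
    return(sp::point.in.polygon(q[, 1], q[, 2],
                                vol$hull2d[, 1], vol$hull2d[, 2]) > 0)
  pts <- .gv_def(vol)
  inside <- rep(FALSE, nrow(q))
  for (k in which(vol$kept)) {
    todo <- which(!inside)
    if (length(todo) == 0) break
    v <- pts[vol$simplices[k, ], , drop = FALSE]
    inside[todo] <- .in_simplex(v, q[todo, , drop = FALSE])
  }
  inside
}

#' Enclosed measure of a growth volume
#' @param vol a [growth_volume()]
#' @return area (um^2, 2D) or volume (um^3, 3D)
#' @export
gv_measure <- function(vol) vol$measure

#' Distance from points to a growth volume
#'
#' Zero for contained points, otherwise the distance to the nearest defining
#' point of the volume (a conservative proxy for the distance to the
#' boundary, adequate for proximity masks).
#'
#' @param vol a [growth_volume()]
#' @param q query points (`m x 3`)
#' @return numeric vector of distances, micrometres
#' @export
gv_distance <- function(vol, q) {
  qp <- .gv_pts(vol, q)
  pts <- .gv_def(vol)
  d2 <- outer(rowSums(qp^2), rowSums(pts^2), "+") - 2 * qp %*% t(pts)
  d <- sqrt(pmax(0, apply(d2, 1, min)))
  d[gv_contains(vol, q)] <- 0
  d
}

#' Chord length of a line inside a growth volume
#'
#' Total length of the intersection of the infinite line through `origin`
#' with direction `direction` and the kept alpha-complex (a union of
#' interior-disjoint simplices, so per-simplex clipped intervals are merged
#' before summing).
#'
#' @param vol a [growth_volume()]
#' @param origin a 3-vector on the line
#' @param direction a 3-vector (need not be unit length)
#' @return chord length in micrometres (0 if the line misses the volume)
#' @export
gv_chord_length <- function(vol, origin, direction) {
  o <- drop(.gv_pts(vol, matrix(origin, nrow = 1)))
  u <- as.numeric(direction)
  if (vol$is2d) u <- u[1:2]
  nu <- sqrt(sum(u^2))
  if (nu < 1e-12) stop("direction must be non-zero")
  u <- u / nu
  pts <- .gv_def(vol)
  ivs <- list()
  for (k in which(vol$kept)) {
    v <- pts[vol$simplices[k, ], , drop = FALSE]
    iv <- .clip_line_simplex(v, o, u)
    if (!is.null(iv) && iv[2] > iv[1]) ivs[[length(ivs) + 1L]] <- iv
  }
  if (length(ivs) == 0) return(0)
  .interval_union_length(do.call(rbind, ivs))
}

## Convex-hull-preserving thinning of a dense point cloud before building an
## alpha = 0 volume: planar sets are reduced to their hull vertices, 3D sets
## deterministically subsampled with the coordinate extremes kept.
.thin_for_hull <- function(pts, max_pts = 400L) {
  pts <- as.matrix(pts)
  if (ncol(pts) == 2) pts <- cbind(pts, 0)
  ext <- apply(pts, 2, function(v) diff(range(v)))
  if (ext[3] <= 1e-6 * max(ext, 1)) {
    h <- grDevices::chull(pts[, 1], pts[, 2])
    return(pts[h, , drop = FALSE])
  }
  if (nrow(pts) <= max_pts) return(pts)
  extremes <- unique(as.vector(apply(pts, 2, function(v)
    c(which.min(v), which.max(v)))))
  keep <- unique(c(extremes,
                   round(seq(1, nrow(pts), length.out = max_pts))))
  pts[sort(keep), , drop = FALSE]
}

#' Alpha-shape boundary volume of a point cloud
#'
#' Convenience wrapper naming the morphometric operation: builds the
#' [growth_volume()] enclosing `points` at tightness `alpha` (`alpha = 0` is
#' the convex hull, `alpha = 1` the tightest boundary still containing all
#' points).
#'
#' @inheritParams growth_volume
#' @return a [growth_volume()]
#' @export
boundary_volume <- function(points, alpha = 0) growth_volume(points, alpha)
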