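## Simplicial geometry backend for growth volumes.
##
## 2D point sets are triangulated with deldir (Delaunay); 3D point sets are
## tetrahedralised with scipy.spatial.Delaunay through a python subprocess
## (the only Delaunay-3D implementation available in this stack). Everything
## downstream — alpha filtering, containment, measure, chords — works on the
## resulting simplex index matrix and is implemented here.

.delaunay_2d <- function(pts) {
  dd <- deldir::deldir(pts[, 1], pts[, 2], suppressMsge = TRUE)
  tl <- deldir::triang.list(dd)
  if (length(tl) == 0) stop("degenerate point set: 2D triangulation is empty")
  t(vapply(tl, function(tr) as.integer(tr$ptNum), integer(3)))
}

.delaunay_3d <- function(pts) {
  exe <- Sys.which("python")
  if (!nzchar(exe)) exe <- Sys.which("python3")
  if (!nzchar(exe))
    stop("3D growth volumes need a 'python' interpreter with scipy on the PATH")
  fin <- tempfile(fileext = ".txt")
  fout <- tempfile(fileext = ".txt")
  fscript <- tempfile(fileext = ".py")
  on.exit(unlink(c(fin, fout, fscript)), add = TRUE)
  utils::write.table(pts, fin, row.names = FALSE, col.names = FALSE)
  writeLines(c(
    "import sys",
    "import numpy as np",
    "from scipy.spatial import Delaunay",
    "p = np.loadtxt(sys.argv[1], ndmin=2)",
    "d = Delaunay(p)",
    "np.savetxt(sys.argv[2], d.simplices + 1, fmt='%d')"), fscript)
  status <- system2(exe, c(fscript, fin, fout), stdout = FALSE, stderr = FALSE)
  if (status != 0 || !file.exists(fout))
    stop("degenerate point set: 3D Delaunay tetrahedralisation failed")
  m <- as.matrix(utils::read.table(fout))
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  m
}

## circumradius of each simplex (rows of idx) over point matrix pts (n x d)
.circumradii <- function(pts, idx) {
  d <- ncol(pts)
  apply(idx, 1, function(s) {
    v <- pts[s, , drop = FALSE]
    A <- sweep(v[-1, , drop = FALSE], 2, v[1, ])
    b <- 0.5 * rowSums(A * A)
    cc <- tryCatch(solve(A %*% t(A), b), error = function(e) NULL)
    if (is.null(cc)) return(Inf)            # degenerate (flat) simplex
    centre <- v[1, ] + drop(t(A) %*% cc)
    sqrt(sum((centre - v[1, ])^2))
  })
}

## unsigned measure (area / volume) of each simplex
.simplex_measures <- function(pts, idx) {
  d <- ncol(pts)
  apply(idx, 1, function(s) {
    v <- pts[s, , drop = FALSE]
    A <- sweep(v[-1, , drop = FALSE], 2, v[1, ])
    abs(det(A)) / factorial(d)
  })
}

## barycentric containment test: which of the query points (m x d) lie in the
## simplex with vertex matrix v ((d+1) x d)?  tol absorbs boundary cases.
.in_simplex <- function(v, q, tol = 1e-9) {
  d <- ncol(v)
  A <- t(sweep(v[-1, , drop = FALSE], 2, v[1, ]))   # d x d
  Ai <- tryCatch(solve(A), error = function(e) NULL)
  if (is.null(Ai)) return(rep(FALSE, nrow(q)))
  lam <- sweep(q, 2, v[1, ]) %*% t(Ai)              # m x d barycentric coords
  ok <- rowSums(lam < -tol) == 0 & (1 - rowSums(lam)) >= -tol
  ok
}

## clip the line  x = o + t*u  against one simplex; returns c(t0, t1) or NULL
.clip_line_simplex <- function(v, o, u, tol = 1e-12) {
  d <- ncol(v)
  lo <- -Inf; hi <- Inf
  for (i in seq_len(d + 1)) {
    face <- v[-i, , drop = FALSE]
    inside <- v[i, ]
    ## normal of the facet hyperplane
    if (d == 2) {
      e <- face[2, ] - face[1, ]
      nrm <- c(-e[2], e[1])
    } else {
      e1 <- face[2, ] - face[1, ]; e2 <- face[3, ] - face[1, ]
      nrm <- c(e1[2] * e2[3] - e1[3] * e2[2],
               e1[3] * e2[1] - e1[1] * e2[3],
               e1[1] * e2[2] - e1[2] * e2[1])
    }
    if (sum(nrm * (inside - face[1, ])) > 0) nrm <- -nrm  # outward
    num <- sum(nrm * (face[1, ] - o))
    den <- sum(nrm * u)
    if (abs(den) < tol) {
      if (sum(nrm * (o - face[1, ])) > 0) return(NULL)    # parallel, outside
    } else {
      t0 <- num / den
      if (den > 0) hi <- min(hi, t0) else lo <- max(lo, t0)
      if (lo > hi) return(NULL)
    }
  }
  c(lo, hi)
}

## total length of the union of 1D intervals (2-column matrix lo, hi)
.interval_union_length <- function(iv) {
  if (is.null(iv) || nrow(iv) == 0) return(0)
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  tot <- 0; cur_lo <- iv[1, 1]; cur_hi <- iv[1, 2]
  if (nrow(iv) > 1) for (i in 2:nrow(iv)) {
    if (iv[i, 1] > cur_hi) {
      tot <- tot + (cur_hi - cur_lo)
      cur_lo <- iv[i, 1]; cur_hi <- iv[i, 2]
    } else cur_hi <- max(cur_hi, iv[i, 2])
  }
  tot + (cur_hi - cur_lo)
}
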