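test_that("branch statistics agree with hand counts and a brute-force recount", {
  y0 <- y_tree(a = 10, b = 10)
  s <- branch_stats(y0)
  expect_equal(s$n_branch_points, 1)
  expect_equal(s$total_length, 30)
  expect_equal(s$mean_segment_length, 10)

  cab <- cable_tree(n = 6, len = 50)
  s2 <- branch_stats(cab)
  expect_equal(s2$n_branch_points, 0)
  expect_equal(s2$mean_segment_length, s2$total_length)

  for (seed in 1:5) {
    tr <- make_synthetic_tree("sphere", N = 25, bf = runif(1), seed = seed,
                              radius = 60, taper = FALSE)
    s3 <- branch_stats(tr)
    o <- recount_stats(tr)
    expect_equal(s3$n_branch_points, o$n_branch_points)
    expect_equal(s3$total_length, o$total_length, tolerance = 1e-9)
    expect_equal(s3$n_segments, o$n_segments)
  }
})

test_that("mean segment length times segment count reproduces total length", {
  tr <- small_sphere_tree()
  s <- branch_stats(tr)
  expect_equal(s$mean_segment_length * s$n_segments, s$total_length,
               tolerance = 1e-9)
})

test_that("Sholl crossings match the per-edge geometric count", {
  cab <- resample_tree(cable_tree(n = 2, len = 100), 1)
  s <- sholl(cab, 10)
  expect_equal(s$radii, seq(10, 100, 10))
  expect_equal(s$counts, rep(1, 10))

  ## tree entirely inside the first shell
  tiny <- cable_tree(n = 3, len = 4)
  s2 <- sholl(tiny, 10)
  expect_length(s2$counts, 0)

  ## mirroring a tree doubles every count
  tr <- small_sphere_tree()
  nd <- tr$nodes
  mir <- nd[-1, ]
  mir$x <- 2 * nd$x[1] - mir$x + 1e-7   # offset avoids duplicate positions
  mir$id <- mir$id + n_nodes(tr) - 1L
  mir$parent <- ifelse(mir$parent == 1L, 1L, mir$parent + n_nodes(tr) - 1L)
  dbl <- morph_tree(rbind(nd, mir))
  s3 <- sholl(tr, 10); s4 <- sholl(dbl, 10)
  expect_equal(s4$counts[seq_along(s3$counts)], 2 * s3$counts)

  expect_error(sholl(tr, -1), "positive")
})

test_that("root angles are 0 for radial cable and pi/2 for perpendicular edges", {
  cab <- cable_tree(n = 11, len = 100)
  expect_equal(max(abs(root_angle_distribution(cab))), 0, tolerance = 1e-9)
  ## an edge moving perpendicular to the away-from-root direction
  nd <- data.frame(id = 1:3, label = c("soma", "basal", "basal"),
                   x = c(0, 10, 10), y = c(0, 0, 1e-6), z = 0,
                   radius = 1, parent = c(-1L, 1L, 2L))
  ang <- root_angle_distribution(morph_tree(nd))
  expect_equal(ang[2], pi / 2, tolerance = 1e-3)
})

test_that("trees grown at high bf have smaller mean root angle", {
  angs <- vapply(c(0.1, 0.9), function(b) {
    mean(vapply(1:8, function(s)
      mean(root_angle_distribution(
        make_synthetic_tree("disc2D", N = 80, bf = b, seed = 100 + s,
                            radius = 100, taper = FALSE))), numeric(1)))
  }, numeric(1))
  expect_lt(angs[2], angs[1])
})

test_that("rmse_percent follows its closed form", {
  expect_equal(rmse_percent(c(5, 5, 5), 5), 0)
  expect_equal(rmse_percent(c(0, 2 * 7), 7), 100)
  expect_error(rmse_percent(1:3, 0), "non-zero")
})

test_that("discrete Frechet distance matches brute-force coupling enumeration", {
  P <- matrix(c(0, 0, 1, 0, 2, 0), ncol = 2, byrow = TRUE)
  Q <- matrix(c(0, 1, 2, 1), ncol = 2, byrow = TRUE)
  expect_equal(discrete_frechet(P, Q), frechet_brute(P, Q))
  expect_equal(discrete_frechet(P, P), 0)
  expect_equal(discrete_frechet(matrix(c(0, 0), 1), matrix(c(3, 4), 1)), 5)
  set.seed(5)
  for (k in 1:5) {
    A <- matrix(runif(10), ncol = 2)
    B <- matrix(runif(8), ncol = 2)
    df <- discrete_frechet(A, B)
    expect_equal(df, frechet_brute(A, B), tolerance = 1e-12)
    expect_equal(df, discrete_frechet(B, A))   # symmetry
    ## lower bound: max over the two matched endpoint pairs
    lb <- max(sqrt(sum((A[1, ] - B[1, ])^2)),
              sqrt(sum((A[nrow(A), ] - B[nrow(B), ])^2)))
    expect_gte(df + 1e-12, lb)
  }
})

test_that("boundary volumes: hull at alpha 0, monotone tightening, containment", {
  cube <- as.matrix(expand.grid(x = c(0, 10), y = c(0, 10), z = c(0, 10)))
  v0 <- boundary_volume(cube, alpha = 0)
  expect_equal(gv_measure(v0), 1000, tolerance = 1e-9)
  expect_true(all(gv_contains(v0, cube)))
  expect_false(gv_contains(v0, matrix(c(20, 5, 5), 1)))

  set.seed(2)
  pts <- matrix(runif(240, 0, 50), ncol = 3)
  meas <- vapply(c(0, 0.5, 1), function(a)
    gv_measure(boundary_volume(pts, a)), numeric(1))
  expect_true(all(diff(meas) <= 1e-9))        # non-increasing in alpha
  v1 <- boundary_volume(pts, 1)
  expect_true(all(gv_contains(v1, pts)))      # defining points always inside
  expect_error(boundary_volume(matrix(c(0, 0, 0, 1, 1, 1), 2, byrow = TRUE)),
               "degenerate|at least")
})

test_that("chord lengths through simple solids are exact", {
  cube <- as.matrix(expand.grid(x = c(0, 1), y = c(0, 1), z = c(0, 1)))
  v <- growth_volume(cube)
  expect_equal(gv_chord_length(v, c(-5, 0.5, 0.5), c(1, 0, 0)), 1,
               tolerance = 1e-9)
  expect_equal(gv_chord_length(v, c(0, 0, 0), c(1, 1, 1)), sqrt(3),
               tolerance = 1e-9)
  sq <- cbind(c(0, 10, 0, 10), c(0, 0, 10, 10))
  v2 <- growth_volume(sq)
  expect_equal(gv_chord_length(v2, c(5, -3, 0), c(0, 1, 0)), 10,
               tolerance = 1e-9)
  expect_equal(gv_chord_length(v2, c(50, 50, 0), c(0, 1, 0)), 0)
})
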