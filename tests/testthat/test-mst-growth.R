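test_that("connection cost follows the optimal-wiring formula", {
  cab <- cable_tree(n = 3, len = 10)                 # nodes at x = 0, 5, 10
  expect_equal(connection_cost(c(10, 2, 0), 3L, cab, bf = 0), 2)
  expect_equal(connection_cost(c(10, 2, 0), 3L, cab, bf = 1), 2 + (10 + 2))
  expect_equal(connection_cost(c(5, 4, 0), 2L, cab, bf = 0.5),
               4 + 0.5 * (5 + 4))
})

test_that("greedy accretion with bf = 0 equals the classical Euclidean MST", {
  root <- morph_tree(data.frame(id = 1L, label = "soma", x = 0, y = 0, z = 0,
                                radius = 5, parent = -1L))
  set.seed(7)
  for (k in 1:20) {
    pts <- matrix(runif(3 * sample(5:40, 1), 0, 100), ncol = 3)
    g <- grow_mst(root, pts, bf = 0, G_thr = Inf)
    expect_equal(total_length(g$tree),
                 prim_mst_length(rbind(c(0, 0, 0), pts)), tolerance = 1e-9)
  }
})

test_that("single target attaches to the nearest node at bf = 0", {
  cab <- cable_tree(n = 3, len = 10)            # nodes at 0, 5, 10
  g <- grow_mst(cab, matrix(c(11, 0, 0), 1), bf = 0)
  expect_equal(g$tree$nodes$parent[4], 3L)      # distance 1 beats 6 and 11
})

test_that("growth threshold blocks unreachable targets", {
  cab <- cable_tree(n = 3, len = 10)
  far <- matrix(c(100, 100, 0, -50, 20, 30), ncol = 3, byrow = TRUE)
  g <- grow_mst(cab, far, bf = 0, G_thr = 5)
  expect_equal(n_nodes(g$tree), 3)
  expect_equal(sort(g$unconnected), 1:2)
  ## targets can become reachable through earlier connections
  chain <- matrix(c(14, 0, 0, 18, 0, 0), ncol = 3, byrow = TRUE)
  g2 <- grow_mst(cab, chain, bf = 0, G_thr = 5)
  expect_length(g2$unconnected, 0)
  expect_equal(g2$order, 1:2)
})

test_that("cable/path-length trade-off is monotone in bf", {
  root <- morph_tree(data.frame(id = 1L, label = "soma", x = 0, y = 0, z = 0,
                                radius = 5, parent = -1L))
  cable <- matrix(0, 20, 2); tip_pl <- matrix(0, 20, 2)
  for (s in 1:20) {
    set.seed(300 + s)
    pts <- matrix(runif(90, -60, 60), ncol = 3)
    for (j in 1:2) {
      b <- c(0, 1)[j]
      g <- grow_mst(root, pts, bf = b, G_thr = Inf)
      cable[s, j] <- total_length(g$tree)
      tips <- terminal_ids(g$tree)
      tip_pl[s, j] <- mean(path_length(g$tree, tips))
    }
  }
  expect_gte(mean(cable[, 2]), mean(cable[, 1]))
  expect_lte(mean(tip_pl[, 2]), mean(tip_pl[, 1]))
})

test_that("seed tree nodes are immutable under growth", {
  tr <- small_sphere_tree()
  set.seed(9)
  pts <- matrix(runif(60, -80, 80), ncol = 3)
  g <- grow_mst(tr, pts, bf = 0.5, G_thr = Inf)
  expect_identical(g$tree$nodes[seq_len(n_nodes(tr)), ], tr$nodes)
})

test_that("growth order is a replayable accretion sequence", {
  root <- morph_tree(data.frame(id = 1L, label = "soma", x = 0, y = 0, z = 0,
                                radius = 5, parent = -1L))
  set.seed(11)
  pts <- matrix(runif(45, 0, 50), ncol = 3)
  g <- grow_mst(root, pts, bf = 0.3, G_thr = Inf)
  ord <- growth_order(g)
  expect_length(ord, 15)
  ## first connected target is the global minimum-cost pair at step 1
  d0 <- sqrt(rowSums(pts^2))
  expect_equal(ord[1], which.min(d0 + 0.3 * d0))
  ## replaying: every new node's parent already existed
  n0 <- 1
  for (i in seq_along(g$new_ids))
    expect_lt(g$tree$nodes$parent[g$new_ids[i]], g$new_ids[i])
  ## replay reproduces the tree
  g2 <- grow_mst(root, pts[ord, , drop = FALSE], bf = 0.3, G_thr = Inf)
  expect_equal(sort(node_xyz(g2$tree)[, 1]), sort(node_xyz(g$tree)[, 1]),
               tolerance = 1e-12)
  expect_equal(total_length(g2$tree), total_length(g$tree), tolerance = 1e-9)
  expect_error(grow_mst(root, pts, attach_ids = integer(0)), "non-empty")
})
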