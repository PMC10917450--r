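test_that("SWC parsing maps columns, labels and topology correctly", {
  txt <- c("# comment", "1 1 0 0 0 5 -1", "2 3 0 0 10 1 1", "3 3 0 0 20 1 2")
  tr <- read_swc(paste(txt, collapse = "\n"))
  expect_equal(n_nodes(tr), 3)
  expect_equal(tr$nodes$label, c("soma", "basal", "basal"))
  expect_equal(total_length(tr), 20)
  expect_equal(tr$nodes$parent, c(-1L, 1L, 2L))
})

test_that("SWC read/write round-trip is node-exact", {
  tr <- small_sphere_tree()
  tr$nodes$cut[terminal_ids(tr)[1]] <- TRUE
  txt <- write_swc(tr)
  expect_true(any(grepl("^#cut:", txt)))
  tr2 <- read_swc(paste(txt, collapse = "\n"))
  expect_equal(n_nodes(tr2), n_nodes(tr))
  for (col in c("x", "y", "z", "radius"))
    expect_equal(tr2$nodes[[col]], tr$nodes[[col]], tolerance = 1e-6)
  expect_identical(tr2$nodes$parent, tr$nodes$parent)
  expect_identical(which(tr2$nodes$cut), which(tr$nodes$cut))
})

test_that("malformed SWC inputs are rejected with format errors", {
  expect_error(read_swc("1 1 0 0 0 5 -1\n5 3 0 0 1 1 99"), "dangling")
  expect_error(read_swc("1 1 0 0 0 5 -1\n2 1 1 0 0 5 -1"), "[Mm]ultiple roots")
  expect_error(read_swc("1 1 0 0 0 0 -1"), "radius")
  expect_error(read_swc("1 1 0 0 0 5"), "7 columns")
  expect_error(write_swc(structure(list(nodes = data.frame()),
                                   class = "morph_tree")), "empty")
})

test_that("resampling subdivides to spacing, preserving endpoints and length", {
  cab <- cable_tree(n = 2, len = 10)
  rs <- resample_tree(cab, 1)
  expect_equal(n_nodes(rs), 11)
  expect_equal(total_length(rs), 10, tolerance = 1e-9)
  expect_equal(unname(node_xyz(rs)[11, 1]), 10)

  ## spacing >= total length leaves topological points unchanged
  y0 <- y_tree()
  rs2 <- resample_tree(y0, 1000)
  expect_equal(node_xyz(rs2), node_xyz(y0))

  ## branch point count is invariant under resampling; lengths within 1%
  tr <- small_sphere_tree()
  rs3 <- resample_tree(tr, 2.5)
  expect_equal(length(branch_point_ids(rs3)), length(branch_point_ids(tr)))
  expect_lt(abs(total_length(rs3) - total_length(tr)) / total_length(tr), 0.01)
  expect_true(all(dendrepair:::.edge_lengths(rs3)[-1] <= 2.5 + 1e-9))
})

test_that("delete_subtree conserves nodes and cable across the two parts", {
  y0 <- y_tree(a = 10, b = 10)
  parts <- delete_subtree(y0, 3L)
  expect_equal(n_nodes(parts$remaining) + n_nodes(parts$severed), n_nodes(y0))
  expect_equal(length(branch_point_ids(parts$remaining)), 0)

  cab <- cable_tree(n = 3, len = 20)
  parts2 <- delete_subtree(cab, 2L)
  expect_equal(n_nodes(parts2$severed), 2)

  tr <- small_sphere_tree()
  b <- branch_point_ids(tr)[3]
  stem_edge <- dendrepair:::.edge_lengths(tr)[b]
  parts3 <- delete_subtree(tr, b)
  expect_equal(total_length(parts3$remaining) + total_length(parts3$severed) +
                 stem_edge, total_length(tr), tolerance = 1e-9)
  expect_error(delete_subtree(tr, 1L), "root")
})

test_that("path_length matches a brute-force edge walk", {
  cab <- cable_tree(n = 5, len = 40)
  expect_equal(path_length(cab, 1L), 0)
  expect_equal(path_length(cab, 5L), 40)
  tr <- small_sphere_tree()
  xyz <- node_xyz(tr)
  walk <- function(i) {
    tot <- 0
    while (tr$nodes$parent[i] > 0) {
      p <- tr$nodes$parent[i]
      tot <- tot + sqrt(sum((xyz[i, ] - xyz[p, ])^2))
      i <- p
    }
    tot
  }
  ids <- c(terminal_ids(tr)[1:5], branch_point_ids(tr)[1:3])
  expect_equal(path_length(tr, ids), vapply(ids, walk, numeric(1)),
               tolerance = 1e-9)
  expect_error(path_length(tr, n_nodes(tr) + 10L), "unknown")
})

test_that("constructor enforces morphology invariants", {
  nd <- data.frame(id = 1:2, label = "basal", x = 0, y = 0, z = 0,
                   radius = 1, parent = c(-1L, 1L))
  expect_s3_class(morph_tree(nd), "morph_tree")
  nd_bad <- nd; nd_bad$radius[2] <- -1
  expect_error(morph_tree(nd_bad), "radii")
  nd_dup <- nd; nd_dup$id <- c(1L, 1L)
  expect_error(morph_tree(nd_dup), "duplicate")
  ## unordered ids are renumbered parent-before-child
  nd_shuf <- data.frame(id = c(5L, 2L, 9L), label = "basal",
                        x = c(1, 0, 2), y = 0, z = 0, radius = 1,
                        parent = c(2L, -1L, 5L))
  tr <- morph_tree(nd_shuf)
  expect_identical(tr$nodes$id, 1:3)
  expect_true(all(tr$nodes$parent < tr$nodes$id))
})
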