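test_that("radial star morphology maps to a high balancing factor", {
  expect_gte(estimate_bf(resample_tree(star_tree(), 1)), 0.9)
})

test_that("balancing factor is recovered from generated morphologies", {
  for (b in c(0.2, 0.8)) {
    est <- mean(vapply(1:6, function(s)
      estimate_bf(make_synthetic_tree("sphere", N = 150, bf = b,
                                      seed = 600 + s, radius = 100)),
      numeric(1)))
    expect_lt(abs(est - b), 0.2)
  }
})

test_that("tiny trees fall back to bf = 0.5 with a warning", {
  expect_warning(b <- estimate_bf(y_tree()), "20 nodes")
  expect_equal(b, 0.5)
})

test_that("growth threshold equals the root-through-midpoint chord", {
  ## sphere of boundary points centred on the root: chord = diameter
  th <- seq(0, pi, length.out = 12)[-c(1, 12)]
  ph <- seq(0, 2 * pi, length.out = 17)[-17]
  sph <- 30 * cbind(as.vector(outer(sin(th), cos(ph))),
                    as.vector(outer(sin(th), sin(ph))),
                    rep(cos(th), times = length(ph)))
  sph <- rbind(sph, c(0, 0, 30), c(0, 0, -30))
  v <- growth_volume(sph)
  expect_equal(growth_threshold(v, c(0, 0, 0)), 60, tolerance = 0.05 * 60)

  ## octahedron with the root on its axis: chord is the full diameter
  oct <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
               c(0, 0, 1), c(0, 0, -1))
  vo <- growth_volume(oct)
  expect_equal(growth_threshold(vo, c(0, 0, -3)), 2, tolerance = 1e-9)

  ## disjoint volume in a direction the root-line misses entirely
  sq <- cbind(c(10, 11, 10, 11), c(10, 10, 11, 11))
  expect_error(growth_threshold(growth_volume(sq), c(-100, 10.5, 0)), NA)
})

test_that("target count scales with volume measure and branch density", {
  tr <- small_sphere_tree()
  sq <- function(s) growth_volume(cbind(c(0, s, 0, s), c(0, 0, s, s)))
  n1 <- estimate_target_count(tr, sq(50))
  n2 <- estimate_target_count(tr, sq(50 * sqrt(2)))   # doubled area
  expect_gte(n1, 1)
  expect_lt(abs(n2 - 2 * n1), max(2, 0.1 * n2))
  ## direct arithmetic: Npts ~ 2 * (NBr + tips) when |V| = hull measure
  hull <- growth_volume(node_xyz(tr))
  topo <- length(branch_point_ids(tr)) + length(terminal_ids(tr))
  expect_equal(estimate_target_count(tr, hull), 2 * topo, tolerance = 2)
})

test_that("target distribution respects volume, margin and density", {
  sq <- growth_volume(cbind(c(0, 100, 0, 100), c(0, 0, 100, 100)))
  pts <- distribute_targets(sq, 200, seed = 4)
  expect_equal(nrow(pts), 200)
  expect_true(all(gv_contains(sq, pts)))

  ## margin R_d from exclusion points
  excl <- cbind(50, 50, 0)
  pts2 <- distribute_targets(sq, 100, exclusion = excl, R_d = 30, seed = 4)
  expect_true(all(sqrt((pts2[, 1] - 50)^2 + (pts2[, 2] - 50)^2) >= 30))
  expect_error(distribute_targets(sq, 5, exclusion = excl, R_d = 500,
                                  seed = 1, max_tries = 50), "could not place")

  ## two-cluster density: most points near the cluster centres
  dens <- rbind(matrix(rnorm(40, 25, 3), ncol = 2),
                matrix(rnorm(40, 75, 3), ncol = 2))
  dens <- cbind(dens, 0)
  pts3 <- distribute_targets(sq, 500, density_points = dens, seed = 9)
  d1 <- sqrt((pts3[, 1] - 25)^2 + (pts3[, 2] - 25)^2)
  d2 <- sqrt((pts3[, 1] - 75)^2 + (pts3[, 2] - 75)^2)
  near <- mean(pmin(d1, d2) < 25)
  expect_gte(near, 0.7)

  ## reproducibility
  expect_identical(distribute_targets(sq, 50, seed = 11),
                   distribute_targets(sq, 50, seed = 11))
})

test_that("cut terminals are selected by flag and proximity to the volume", {
  demo <- make_demo_2d()
  tr <- demo$tree
  ## volume around the flagged terminal at (50, -15)
  vol <- growth_volume(cbind(c(45, 75, 45, 75), c(-30, -30, 10, 10)))
  sel <- find_cut_terminals(tr, vol)
  expect_true(7L %in% sel)
  expect_false(12L %in% sel)          # flagged but on the far side
  ## no flags: heuristic picks thick terminals near V, warns
  tr2 <- tr; tr2$nodes$cut <- FALSE
  tr2$nodes$radius[7] <- 2            # conspicuously thick terminal near V
  expect_warning(sel2 <- find_cut_terminals(tr2, vol), "putative")
  expect_true(all(sel2 %in% terminal_ids(tr2)))
})

test_that("main branch grows straight to ~95% of the chord", {
  cab <- cable_tree(n = 11, len = 10)
  cab$nodes$cut[11] <- TRUE
  box <- growth_volume(cbind(c(10, 110, 10, 110), c(-50, -50, 50, 50)))
  g_thr <- growth_threshold(box, c(0, 0, 0))
  mg <- grow_main_branch(cab, box, 11L, G_thr = g_thr, spacing = 1)
  main_len <- total_length(mg$tree) - total_length(cab)
  expect_lt(abs(main_len - 0.95 * g_thr), 2)
  expect_true(all(mg$tree$nodes$label[mg$new_ids] == "apical"))
  ## thickest of two cut terminals is chosen
  y2 <- y_tree(a = 5, b = 5)
  y2$nodes$cut[3:4] <- TRUE
  y2$nodes$radius[3] <- 2; y2$nodes$radius[4] <- 1
  vol2 <- growth_volume(cbind(c(5, 60, 5, 60), c(-30, -30, 30, 30)))
  mg2 <- grow_main_branch(y2, vol2, c(3L, 4L), spacing = 1)
  expect_equal(mg2$tree$nodes$parent[mg2$new_ids[1]], 3L)
  expect_error(grow_main_branch(y2, vol2, integer(0)), "non-empty")
})

test_that("jitter is amplitude-bounded, autocorrelated and pins junctions", {
  tr <- resample_tree(cable_tree(n = 2, len = 200), 1)
  new_ids <- 3:n_nodes(tr)                 # keep node 2 as the junction pin
  j0 <- jitter_new_nodes(tr, new_ids, amplitude = 0, seed = 2)
  expect_identical(j0$nodes, tr$nodes)
  j1 <- jitter_new_nodes(tr, new_ids, amplitude = 1, window = 5, seed = 2)
  disp <- node_xyz(j1) - node_xyz(tr)
  expect_identical(j1$nodes$parent, tr$nodes$parent)
  expect_equal(unname(disp[1:2, ]), matrix(0, 2, 3))  # pinned
  rms <- sqrt(mean(rowSums(disp[new_ids, ]^2) / 3))
  expect_gt(rms, 0)
  expect_lte(rms, 1)                 # smoothing only reduces the variance
  ## displacements are autocorrelated over roughly the window length
  dy <- disp[new_ids, 2]
  ac <- stats::acf(dy, lag.max = 3, plot = FALSE)$acf[4]
  expect_gt(ac, 0.3)
})

test_that("quadratic taper parameters are recovered from exact input", {
  cab <- resample_tree(cable_tree(n = 2, len = 100), 1)
  pl <- path_length(cab, seq_len(n_nodes(cab)))
  P <- max(pl)
  cab$nodes$radius <- pmax((3 * (1 - pl / P)^2 + 0.6) / 2, 1e-3)
  ft <- fit_taper(cab)
  expect_equal(ft$scale, 3, tolerance = 1e-6)
  expect_equal(ft$offset, 0.6, tolerance = 1e-6)
  ## constant-diameter input
  cab2 <- resample_tree(cable_tree(n = 2, len = 100, radius = 0.7), 1)
  ft2 <- fit_taper(cab2)
  expect_equal(ft2$scale, 0, tolerance = 1e-9)
  expect_equal(ft2$offset, 1.4, tolerance = 1e-9)
  expect_lte(ft2$d_min, 1.4 + 1e-9)
})

test_that("applied taper floors at d_min and is monotone toward the tips", {
  tr <- small_sphere_tree()
  new_ids <- setdiff(seq_len(n_nodes(tr)), 1L)
  tp <- list(scale = 2, offset = 0.1, d_min = 0.4)
  out <- apply_taper(tr, new_ids, tp)
  expect_true(all(2 * out$nodes$radius[new_ids] >= 0.4 - 1e-12))
  par <- out$nodes$parent
  for (i in new_ids) if (par[i] %in% new_ids)
    expect_lte(out$nodes$radius[i], out$nodes$radius[par[i]] + 1e-12)
})

test_that("pruning removes the shortest all-new terminal segments only", {
  ## cable with two new terminal branches: 10 um and 25 um
  base <- cable_tree(n = 6, len = 50)
  nd <- base$nodes
  add <- data.frame(id = 7:9, label = "basal",
                    x = c(20, 20, 20), y = c(10, 15, 25), z = 0,
                    radius = 0.5, parent = c(3L, 7L, 8L), cut = FALSE)
  add2 <- data.frame(id = 10L, label = "basal", x = 40, y = 10, z = 0,
                     radius = 0.5, parent = 5L, cut = FALSE)
  tr <- morph_tree(rbind(nd, add, add2))
  new_ids <- 7:10
  pr <- prune_to_length(tr, new_ids, total_length(tr))       # no-op
  expect_equal(n_nodes(pr$tree), 10)
  pr2 <- prune_to_length(tr, new_ids, total_length(tr) - 5)
  expect_equal(n_nodes(pr2$tree), 9)          # 10 um branch removed first
  expect_equal(total_length(pr2$tree), 75)
  expect_warning(pr3 <- prune_to_length(tr, new_ids, 10), "input nodes")
  expect_equal(n_nodes(pr3$tree), 6)          # input intact
})

test_that("fix_tree matches a requested branch-point count and keeps input intact", {
  tr <- classIV_fixture()
  rc <- random_cut(tr, seed = 21)
  rep <- fix_tree(rc$tree, rc$lesion$severed_hull,
                  growth_params(target_nbr = rc$lesion$severed_length / 30 + 20,
                                seed = 3))
  n_in <- n_nodes(rep$input)
  expect_identical(rep$tree$nodes[seq_len(n_in), ], rep$input$nodes)
  expect_gte(rep$stats_after$n_branch_points,
             rep$stats_before$n_branch_points)
  expect_true(all(rep$new_ids > n_in))
})

test_that("conserved growth descends exclusively from cut terminals", {
  tr <- make_synthetic_tree("disc2D", N = 120, bf = 0.3, seed = 31,
                            radius = 100)
  for (s in 1:3) {
    rc <- random_cut(tr, seed = 40 + s)
    rep <- fix_tree(rc$tree, rc$lesion$severed_hull,
                    growth_params(mode = "conserved", seed = s))
    stem <- which(rep$input$nodes$cut)
    desc <- unlist(lapply(stem, function(i) subtree_ids(rep$tree, i)))
    expect_true(all(rep$new_ids %in% desc))
  }
})

test_that("identical seeds give byte-identical repaired SWC output", {
  tr <- make_synthetic_tree("disc2D", N = 100, bf = 0.3, seed = 8,
                            radius = 100)
  rc <- random_cut(tr, seed = 5)
  p <- growth_params(seed = 77)
  a <- fix_tree(rc$tree, rc$lesion$severed_hull, p)
  b <- fix_tree(rc$tree, rc$lesion$severed_hull, p)
  expect_identical(write_swc(a$tree), write_swc(b$tree))
})

test_that("demo repairs differ between the bf extremes", {
  demo <- make_demo_2d()
  vol <- growth_volume(cbind(c(45, 90, 45, 90), c(-40, -40, 25, 25)))
  reps <- lapply(c(0, 1), function(b)
    fix_tree(demo$tree, vol, growth_params(bf = b, npts = 30, seed = 2,
                                           mode = "conserved")))
  expect_true(total_length(reps[[1]]$tree) != total_length(reps[[2]]$tree) ||
                reps[[1]]$stats_after$n_branch_points !=
                reps[[2]]$stats_after$n_branch_points)
  expect_lte(total_length(reps[[1]]$tree), total_length(reps[[2]]$tree))
})
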