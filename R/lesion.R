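## In-silico dendriotomy: random subtree cuts, repair into the vacated
## volume, and regeneration-versus-invasion quantification.

#' Sever a random dendritic subtree
#'
#' Picks uniformly among branch points whose subtree removes between `L_min`
#' and `L_max` micrometres of cable (subtree edges plus the stem edge), cuts
#' there with [delete_subtree()], and flags the resulting terminal of the
#' remaining tree as a cut end. The record keeps the severed part and the
#' convex hull of its nodes — the volume the regrowth is later asked to
#' re-cover.
#'
#' @param tree a [morph_tree()] with at least one qualifying branch point
#' @param L_min,L_max severed-length bounds, um (defaults 50 and 1000)
#' @param seed integer seed
#' @return list with `tree` (the cut [morph_tree()], one terminal flagged
#'   cut) and `lesion`, an object of class `lesion_record`: list with
#'   `stem_id` (the severed branch point, id in the original tree),
#'   `cut_terminal` (id of the flagged terminal in the cut tree),
#'   `severed_tree`, `severed_length` (um), `severed_hull` (a
#'   [growth_volume()], alpha = 0) and `seed`.
#' @export
random_cut <- function(tree, L_min = 50, L_max = 1000, seed = 1L) {
  elen <- .edge_lengths(tree)
  bps <- branch_point_ids(tree)
  bps <- setdiff(bps, 1L)
  if (length(bps) == 0) stop("tree has no branch points to cut at")
  ## cable removed by cutting at each node: one reverse accumulation pass
  acc <- elen
  par <- tree$nodes$parent
  for (i in n_nodes(tree):2) acc[par[i]] <- acc[par[i]] + acc[i]
  sub_len <- acc[bps]
  ok <- which(sub_len > L_min & sub_len < L_max)
  if (length(ok) == 0)
    stop("no branch point with severed length in (", L_min, ", ", L_max, ") um")
  .with_seed(seed, {
    for (b_i in sample(ok, length(ok))) {
      b <- bps[b_i]
      parts <- delete_subtree(tree, b)
      hull <- tryCatch(growth_volume(.thin_for_hull(node_xyz(parts$severed)),
                                     alpha = 0),
                       error = function(e) NULL)
      if (is.null(hull)) next                  # degenerate (collinear) subtree
      cut_tree <- parts$remaining
      term <- sum(seq_len(n_nodes(tree))[-subtree_ids(tree, b)] <
                    tree$nodes$parent[b]) + 1L  # new id of the stem's parent
      cut_tree$nodes$cut[term] <- TRUE
      return(list(tree = cut_tree,
                  lesion = structure(list(stem_id = b, cut_terminal = term,
                                          severed_tree = parts$severed,
                                          severed_length = sub_len[b_i],
                                          severed_hull = hull, seed = seed),
                                     class = "lesion_record")))
    }
    stop("every qualifying severed subtree is geometrically degenerate")
  })
}

#' @export
print.lesion_record <- function(x, ...) {
  cat(sprintf("<lesion_record> stem at branch point %d; %.1f um severed (%d nodes)\n",
              x$stem_id, x$severed_length, n_nodes(x$severed_tree)))
  invisible(x)
}

#' Percentage of new material regenerated from the lesioned stem
#'
#' Share of the regrown cable whose path to the root passes through the cut
#' terminal (the lesion stem): 100% means pure regeneration from the severed
#' stem, 0% pure invasion from neighbouring intact branches.
#'
#' @param result a [fix_tree()] result (`dendrite_repair`)
#' @param stem_ids ids, in the repaired tree, of the lesion stem node(s);
#'   defaults to the cut-flagged terminals of the repair's input.
#' @return regeneration percentage in `[0, 100]` (0 when nothing was grown)
#' @export
regeneration_percent <- function(result,
                                 stem_ids = which(result$input$nodes$cut)) {
  stopifnot(inherits(result, "dendrite_repair"))
  if (length(result$new_ids) == 0) return(0)
  elen <- .edge_lengths(result$tree)
  desc <- unique(unlist(lapply(stem_ids, function(s)
    subtree_ids(result$tree, s))))
  new_len <- sum(elen[result$new_ids])
  if (new_len <= 0) return(0)
  100 * sum(elen[intersect(result$new_ids, desc)]) / new_len
}

#' Run the random cut-and-regrow experiment
#'
#' Per trial: sever a random subtree ([random_cut()]), take the convex hull
#' of the severed nodes as the growth volume, distribute target points with
#' an exclusion margin `R_d` away from every point of the lesioned neuron,
#' regrow in biological mode ([fix_tree()]), and record the regeneration
#' percentage and morphometrics. Input-level growth parameters (balancing
#' factor, taper, jitter, topological-point density) are estimated once from
#' the intact tree and reused across trials.
#'
#' @param tree the intact [morph_tree()] to lesion repeatedly
#' @param n_trials number of trials (>= 1)
#' @param params a [growth_params()]; its `R_d` defaults to 2 um here (twice
#'   the resampling spacing) to avoid biasing regrowth toward regeneration
#'   or invasion. `NULL` fields are estimated from the intact tree.
#' @param seed integer seed; trial `i` uses `seed + i`.
#' @return an object of class `lesion_experiment`: list with `table` (one
#'   row per successful trial: trial, seed, stem_id, severed_length_um,
#'   regeneration_pct, nbr_ref, nbr_cut, nbr_rep, total_len_ref,
#'   total_len_cut, total_len_rep), `histogram` (counts over ten 10%-wide
#'   regeneration bins), `stratified` (regeneration by severed-length
#'   quartile) and `n_failed`.
#' @export
run_lesion_experiment <- function(tree, n_trials, params = growth_params(),
                                  seed = 1L) {
  stopifnot(inherits(tree, "morph_tree"), n_trials >= 1)
  base <- resample_tree(tree, params$spacing)
  if (is.null(params$R_d) || params$R_d == 0) params$R_d <- 2 * params$spacing
  if (is.null(params$bf)) params$bf <- estimate_bf(base)
  if (is.null(params$taper)) params$taper <- fit_taper(base)
  if (is.null(params$jitter_amplitude))
    params$jitter_amplitude <- 0.3 * .tortuosity_residual(base)
  n_topo <- length(branch_point_ids(base)) + length(terminal_ids(base))
  hull_measure <- tryCatch(gv_measure(growth_volume(node_xyz(base), alpha = 0)),
                           error = function(e) NA_real_)
  rho <- if (is.finite(hull_measure) && hull_measure > 0)
    n_topo / hull_measure else NA_real_
  ref_stats <- branch_stats(base)
  ref_len <- ref_stats$total_length
  ref_nbr <- ref_stats$n_branch_points

  rows <- list(); n_failed <- 0L
  for (i in seq_len(n_trials)) {
    trial_seed <- seed + i
    row <- tryCatch({
      rc <- random_cut(base, seed = trial_seed)
      vol <- rc$lesion$severed_hull
      p <- params
      p$seed <- trial_seed
      p$mode <- "biological"
      if (is.null(p$npts))
        p$npts <- if (is.finite(rho))
          max(1L, as.integer(round(2 * rho * gv_measure(vol)))) else NULL
      rep <- fix_tree(rc$tree, vol, p)
      st <- rep$stats_after
      data.frame(trial = i, seed = trial_seed,
                 stem_id = rc$lesion$stem_id,
                 severed_length_um = rc$lesion$severed_length,
                 regeneration_pct = regeneration_percent(rep),
                 nbr_ref = ref_nbr,
                 nbr_cut = rep$stats_before$n_branch_points,
                 nbr_rep = st$n_branch_points,
                 total_len_ref = ref_len,
                 total_len_cut = rep$stats_before$total_length,
                 total_len_rep = st$total_length)
    }, error = function(e) NULL)
    if (is.null(row)) n_failed <- n_failed + 1L else
      rows[[length(rows) + 1L]] <- row
  }
  tab <- do.call(rbind, rows)
  brk <- seq(0, 100, by = 10)
  hist_counts <- if (!is.null(tab))
    table(cut(tab$regeneration_pct, brk, include.lowest = TRUE)) else
      table(cut(numeric(0), brk))
  strat <- if (!is.null(tab) && nrow(tab) >= 4) {
    qs <- stats::quantile(tab$severed_length_um, c(0, .25, .5, .75, 1))
    g <- cut(tab$severed_length_um, unique(qs), include.lowest = TRUE)
    do.call(rbind, lapply(split(tab, g), function(s)
      data.frame(severed_length_bin = as.character(g[match(s$trial[1], tab$trial)]),
                 n = nrow(s),
                 mean_regeneration_pct = mean(s$regeneration_pct),
                 pct_full_regeneration = 100 * mean(s$regeneration_pct > 80),
                 pct_full_invasion = 100 * mean(s$regeneration_pct < 10))))
  } else NULL
  if (!is.null(strat)) rownames(strat) <- NULL
  structure(list(table = tab, histogram = hist_counts, stratified = strat,
                 n_failed = n_failed, params = params),
            class = "lesion_experiment")
}

#' @export
print.lesion_experiment <- function(x, ...) {
  n <- if (is.null(x$table)) 0L else nrow(x$table)
  cat(sprintf("<lesion_experiment> %d trials (%d failed)\n", n, x$n_failed))
  if (n > 0) {
    cat(sprintf("  regeneration: median %.1f%%, %.0f%% of trials <10%%, %.0f%% >80%%\n",
                stats::median(x$table$regeneration_pct),
                100 * mean(x$table$regeneration_pct < 10),
                100 * mean(x$table$regeneration_pct > 80)))
  }
  invisible(x)
}
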