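#' Passive membrane specification
#'
#' Passive electrical constants for the steady-state compartmental model.
#' Membrane capacitance plays no role at steady state and is not included.
#' The defaults (Rm = 28 kOhm cm^2, Ra = 150 Ohm cm) are typical passive
#' values for pyramidal neurons; results of [restoration_check()] are
#' comparisons between morphologies, so the constants only set the scale.
#'
#' @param Rm specific membrane resistivity, Ohm cm^2 (> 0)
#' @param Ra axial (cytoplasmic) resistivity, Ohm cm (> 0)
#' @return an object of class `passive_spec`
#' @export
passive_spec <- function(Rm = 28000, Ra = 150) {
  if (Rm <= 0 || Ra <= 0) stop("Rm and Ra must be positive")
  structure(list(Rm = Rm, Ra = Ra), class = "passive_spec")
}

## conductance matrix (Siemens) of the steady-state passive model:
## one compartment per node, frustum axial conductances between neighbours,
## membrane leak from the half-areas of adjacent frusta (plus a spherical
## soma area for a soma-labelled root).
.passive_system <- function(tree, spec) {
  nd <- tree$nodes
  n <- nrow(nd)
  um <- 1e-4                                   # um -> cm
  elen <- .edge_lengths(tree) * um
  r <- nd$radius * um
  has_par <- which(nd$parent > 0)
  par <- nd$parent[has_par]
  r1 <- r[par]; r2 <- r[has_par]; L <- elen[has_par]
  L <- pmax(L, 1e-12)
  g_ax <- pi * r1 * r2 / (spec$Ra * L)         # frustum axial conductance
  slant <- sqrt(L^2 + (r1 - r2)^2)
  a_lat <- pi * (r1 + r2) * slant              # frustum lateral area, cm^2
  area <- numeric(n)
  for (k in seq_along(has_par)) {
    area[par[k]] <- area[par[k]] + a_lat[k] / 2
    area[has_par[k]] <- area[has_par[k]] + a_lat[k] / 2
  }
  if (nd$label[1] == "soma") area[1] <- area[1] + 4 * pi * r[1]^2
  if (all(area <= 0)) stop("degenerate morphology: zero membrane area")
  g_m <- area / spec$Rm
  ii <- c(seq_len(n), has_par, par)
  jj <- c(seq_len(n), par, has_par)
  diagg <- g_m
  for (k in seq_along(has_par)) {
    diagg[par[k]] <- diagg[par[k]] + g_ax[k]
    diagg[has_par[k]] <- diagg[has_par[k]] + g_ax[k]
  }
  xx <- c(diagg, -g_ax, -g_ax)
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
}

#' Steady-state passive input resistance
#'
#' Solves the steady-state passive compartmental linear system (frustum
#' axial conductances between neighbouring nodes, membrane leak per
#' compartment) for a unit current injected at `site` and returns the local
#' voltage per current, i.e. the input resistance. Cutting dendrite removes
#' membrane shunt and therefore always raises the somatic input resistance —
#' the mechanism by which lesioned neurons become hyperexcitable — and a
#' successful repair moves it back toward the reference value.
#'
#' @param tree a [morph_tree()]
#' @param spec a [passive_spec()]
#' @param site node id of the injection site (default: the root)
#' @return input resistance in megaohms
#' @export
input_resistance <- function(tree, spec = passive_spec(), site = 1L) {
  G <- .passive_system(tree, spec)
  n <- n_nodes(tree)
  site <- as.integer(site)
  if (site < 1L || site > n) stop("unknown site id: ", site)
  b <- numeric(n); b[site] <- 1
  v <- tryCatch(as.numeric(Matrix::solve(G, b)),
                error = function(e) stop("singular passive system: ", conditionMessage(e)))
  v[site] / 1e6
}

#' Transfer resistance between two sites
#'
#' Voltage at `site_b` per unit current injected at `site_a`, in megaohms.
#' By reciprocity of the passive system this is symmetric in its sites.
#'
#' @inheritParams input_resistance
#' @param site_a,site_b node ids
#' @return transfer resistance in megaohms
#' @export
transfer_resistance <- function(tree, spec = passive_spec(), site_a, site_b) {
  G <- .passive_system(tree, spec)
  n <- n_nodes(tree)
  b <- numeric(n); b[as.integer(site_a)] <- 1
  v <- as.numeric(Matrix::solve(G, b))
  v[as.integer(site_b)] / 1e6
}

#' Check functional restoration via input resistance
#'
#' Compares the somatic input resistance of a reference, a cut and a
#' repaired morphology. A lesion removes membrane and must raise the input
#' resistance (an excitability proxy); a successful repair brings it back
#' closer to the reference than the cut neuron was.
#'
#' @param reference,cut,repaired [morph_tree()]s
#' @param spec a [passive_spec()]
#' @return an object of class `restoration_report`: list with `R_reference`,
#'   `R_cut`, `R_repaired` (megaohms), `cut_increases` (logical),
#'   `repaired_closer` (logical) and `degenerate` (TRUE when cut and
#'   reference are electrically identical).
#' @export
restoration_check <- function(reference, cut, repaired,
                              spec = passive_spec()) {
  r_ref <- input_resistance(reference, spec)
  r_cut <- input_resistance(cut, spec)
  r_rep <- input_resistance(repaired, spec)
  degen <- isTRUE(all.equal(r_cut, r_ref, tolerance = 1e-12))
  structure(list(R_reference = r_ref, R_cut = r_cut, R_repaired = r_rep,
                 cut_increases = r_cut > r_ref,
                 repaired_closer = abs(r_rep - r_ref) < abs(r_cut - r_ref),
                 degenerate = degen),
            class = "restoration_report")
}

#' @export
print.restoration_report <- function(x, ...) {
  cat(sprintf("<restoration_report> R_in (MOhm): reference %.2f, cut %.2f, repaired %.2f\n",
              x$R_reference, x$R_cut, x$R_repaired))
  cat(sprintf("  cut raises R_in: %s; repair closer to reference than cut: %s%s\n",
              x$cut_increases, x$repaired_closer,
              if (x$degenerate) " (degenerate: cut == reference)" else ""))
  invisible(x)
}

#' @export
format.restoration_report <- function(x, ...) {
  jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA)
}
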