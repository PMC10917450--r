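---
title: "Repairing dendritic arbours by optimal wiring: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Repairing dendritic arbours by optimal wiring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Neuronal reconstructions are routinely incomplete: slicing, limited imaging
volumes and tracing artefacts truncate dendritic trees, and truncated trees
bias every downstream quantity from branch counts to simulated
excitability. `dendrepair` completes such reconstructions by growing
synthetic dendrite into a user-specified region, using the same
optimal-wiring principle that accounts for dendritic morphology across cell
types. This vignette documents the model, the tunable parameters, the
numerical choices, and the limits of what the test suite demonstrates.

## The growth model

A morphology is a rooted tree of 3D nodes with radii (the SWC data model).
Growth proceeds by greedy accretion: given a set of target points in a
growth volume $V$, each step connects the (target, attachment-node) pair
minimising

$$\text{cost} = d \; + \; bf \cdot \big(\mathrm{PL}(v) + d\big),$$

where $d$ is the Euclidean distance from the target to the candidate node
$v$ and $\mathrm{PL}(v)$ is the path length from $v$ to the root, so
$\mathrm{PL}(v) + d$ is the path length the new point would acquire. The
*balancing factor* $bf \in [0, 1]$ trades material cost (total cable)
against conduction cost (path length to the soma): at $bf = 0$ the rule is
exactly Prim's algorithm and produces the Euclidean minimum spanning tree
(the package tests assert equality with an independent Prim implementation
to $10^{-9}$); at $bf = 1$ trees become radial, with longer cable but short
direct paths. A single connection may never span more than the *growth
threshold* $G_{thr}$.

We deliberately evaluate candidate pairs exhaustively (with incremental
caching of per-target minima, which is exact because established costs
never change); a spatial index would only be an optimisation. Ties are
broken lexicographically on (cost, node id, target index), which makes
growth deterministic across platforms. Attachment is node-to-node: trees
are resampled to 1 µm spacing before growth, so the error from not
splitting edges mid-way is bounded by half the spacing.

## The repair pipeline

`fix_tree()` orchestrates a repair. Unset parameters are estimated from the
input neuron:

* **Balancing factor.** The mean of the root-angle distribution (angle
  between each local growth direction and the away-from-root direction)
  decreases monotonically with $bf$. We grow reference trees across the
  grid $bf = 0, 0.1, \dots, 1$ in a matched normalised volume (disc or
  sphere of radius 100 µm, 150 targets, five fixed seeds per grid point),
  fit the mean angle isotonically, and invert. The calibration is computed
  once per session and is dimension-aware, since flat arbours have a
  different angle geometry than space-filling ones. Parameter-recovery
  tests show the estimator is unbiased to well within ±0.1 across
  $bf \in [0.1, 0.9]$; trees of fewer than 20 nodes fall back to
  $bf = 0.5$ with a warning, since their angle statistics are meaningless.
* **Growth threshold.** $Q$ is the midpoint between the centroid of the
  volume's defining points and the defining point farthest from the root
  $R$; $G_{thr}$ is the chord length of the line through $R$ and $Q$ inside
  $V$. For thin sliver volumes this chord can be degenerately small and
  strand every target; when the threshold was estimated (not user-set) the
  pipeline then relaxes it geometrically (doubling, at most six times)
  until growth can proceed. A user-supplied threshold is never overridden.
* **Target count.** Topological points (branch points plus terminations)
  per unit of the input's spanning-field hull measure, scaled to $|V|$, at
  two targets per expected topological point. The factor two only sets the
  starting level: when a desired branch-point count $N_{Br}$ is given
  (e.g. from a reference morphology), the pipeline re-runs growth with
  different target counts — bisection over nested target subsets, then a
  local scan, at most 12 growth evaluations — because $N_{Br}$ is only
  monotone in the target count on average. Nested subsets (the first $k$
  of one fixed sample) keep the search well behaved and deterministic.
  When the requested $N_{Br}$ exceeds what four times the density estimate
  can produce, the range is widened proportionally to the branch-point
  deficit; the estimate is a starting point, not a constraint.
* **Targets.** Monte Carlo rejection sampling inside $V$: uniform
  candidates are thinned by a Gaussian kernel-density weight built from
  the input's branch and termination points, so new targets cluster the
  way the existing arbour does, and must keep a margin $R_d$ from every
  point of the lesioned neuron when one is set. Fewer than five density
  points cannot support a bandwidth estimate and fall back to uniform.
* **Post-processing.** New nodes receive (i) low-pass-filtered spatial
  jitter — per-branch isotropic Gaussian noise smoothed by a centred
  moving average (window 5 nodes), junction nodes pinned; the default
  amplitude is 0.3 × the input's mean inter-node tortuosity residual, so
  perfectly straight synthetic inputs stay straight; (ii) a quadratic
  diameter taper $d(p) = s\,(1 - p/P)^2 + o$ fitted by least squares to
  the input's dendritic nodes per structure label, floored at $d_{min}$,
  the 5th percentile of the input's terminal diameters (tip diameters
  level off to a roughly constant, species-dependent value); and
  (iii) optional pruning to a target total length by repeatedly removing
  the shortest all-new terminal segment, stopping as soon as removing even
  the shortest segment would overshoot by more than the remaining excess.
  Input nodes are never moved, re-diametered or removed.

Two growth modes are supported. *Biological* growth may sprout from any
node within $G_{thr}$ of the volume; *conserved* growth only from
cut-flagged incomplete terminals, which confines all new material to the
severed stems (an invariant the tests check node-by-node). *Main growth*
additionally extends a straight branch from the thickest cut terminal
along the root-through-$Q$ line to 95% of $G_{thr}$ — the geometry of
severed apical trunks of pyramidal cells.

## Growth volumes

Volumes are alpha-complexes over the Delaunay triangulation of their
defining points: `alpha = 0` keeps every simplex (the convex hull);
`alpha = 1` keeps the tightest complex in which every defining point is
still a vertex of a retained simplex; intermediate values interpolate on
that critical-radius scale, so the enclosed measure is non-increasing in
alpha. Containment, measure and line-chord computations all operate on the
retained simplices (interior-disjoint, so per-simplex chord intervals are
merged before summing). Point sets with negligible extent normal to a
plane are treated as 2D. The 2D triangulation uses `deldir`; the 3D
tetrahedralisation is delegated to `scipy.spatial.Delaunay` through a
small subprocess bridge, the only Delaunay-3D implementation in this
software stack. Before building a convex (`alpha = 0`) hull around dense
severed subtrees, the point cloud is thinned to its hull vertices (2D) or
a deterministic subsample retaining the coordinate extremes (3D), which
leaves the hull unchanged (2D) or nearly so while keeping triangulations
small.

## In-silico dendriotomy

`random_cut()` severs a uniformly chosen branch point whose removed cable
(subtree plus stem edge) lies in (50, 1000) µm, flags the resulting
terminal as a cut end, and records the severed part with the convex hull
of its nodes. `run_lesion_experiment()` repeats cut → regrow into the
severed hull → quantify, with target points kept $R_d$ = 2 µm (twice the
resampling spacing) away from the lesioned neuron so that neither
regeneration from the stem nor invasion from neighbouring branches is
favoured by construction. The *regeneration percentage* is the share of
new cable whose root path passes through the cut terminal: 100% is pure
regeneration, 0% pure invasion. On the flat dense synthetic arbour the
distribution is strongly bimodal — a distinct peak of pure invasion and a
broad regime of mostly-regeneration — which is the qualitative behaviour
this protocol is designed to expose.

## Passive electrotonics

The functional check solves the steady-state passive compartmental system:
one compartment per node, frustum axial conductances
$g = \pi r_1 r_2 / (R_a L)$ between neighbours, membrane leak from the
frustum half-areas (plus a spherical surface for a soma-labelled root),
solved sparsely for a unit current at the soma. Defaults
$R_m = 28\,\mathrm{k\Omega\,cm^2}$, $R_a = 150\,\mathrm{\Omega\,cm}$ are
typical pyramidal passive constants; all comparisons are relative, so
they only set the scale. Removing dendrite removes membrane shunt and must
raise the somatic input resistance — the mechanism behind post-lesion
hyperexcitability — and a successful repair moves it back toward the
reference. The discretisation is validated against the sealed-end cable
closed form $R_{in} = R_\infty \coth(L/\lambda)$ to 1% at 1 µm
compartments, and transfer resistances are checked for reciprocity.

## Synthetic study conditions

All tests run without downloads, on generated stand-ins:

* `make_classIV_like()`: a 200 µm disc filled from 800 targets at
  $bf = 0.2$ — flat, dense, space-filling, the regime of larval
  dendritic-arborisation class IV sensory neurons. Used for the 200-trial
  lesion experiment.
* cut-and-repair references: discs of 300 targets, radius 150 µm,
  $bf = 0.3$ (≈ 3.5 mm cable, 70–80 branch points) — large enough that the
  50–1000 µm cut window spans small to severe lesions.
* `make_pyramidal_like()`: spherical basal tree plus an apical cone with a
  straight trunk, for main-growth and labelling behaviour.
* bf-recovery trees: spheres of 150 targets, radius 100 µm, matching the
  calibration geometry, 20 seeds per grid point.

These stand-ins reproduce the *qualitative* regimes (flat dense vs sparse
radial, bimodal regrowth, hyperexcitable cuts) but not the specimen-level
statistics of any real reconstruction: segment-length distributions,
spine-scale roughness, tissue boundaries and multi-neuron competition are
absent. Passing tests therefore demonstrate the machinery and its
invariants, not fidelity to a particular dataset; for real data the same
pipeline ingests SWC files and user-drawn growth volumes.

## Numerical choices and degenerate inputs

* Resampling subdivides (and merges exactly collinear runs) but never
  shifts branch points or terminations; already-conforming trees are
  returned unchanged.
* Sholl analysis uses Euclidean shells of 10 µm by default; a
  parent–child edge contributes one crossing per shell between its two
  node distances (lower bound exclusive, upper inclusive).
* The discrete Fréchet distance is the standard dynamic programme,
  validated against exhaustive coupling enumeration on small curves.
* Simplex circumradii through a linear solve; flat simplices (rank
  deficient, or measure below $10^{-12}$ of the largest) are discarded
  before alpha filtering. Degenerate point sets (collinear, coplanar in
  3D) are rejected with errors rather than repaired silently.
* All randomness flows through explicit integer seeds; a repair with the
  same inputs and seed writes byte-identical SWC.

## Known limitations

* The balancing-factor calibration assumes homogeneous growth statistics;
  heavily pruned or very sparse inputs bias the estimate (the fallback
  warns below 20 nodes, but bias sets in earlier).
* $G_{thr}$ from the root-chord is a blunt instrument for strongly
  non-convex or sliver volumes; the geometric relaxation keeps repairs
  alive but a manual threshold is better there.
* Conserved growth with several cut terminals does not balance material
  between stems; the wiring cost alone decides.
* The passive check is steady-state only: no capacitance, no active
  conductances, no synapses. It orders morphologies by input resistance;
  it does not predict firing.
* Node-to-node attachment slightly overestimates cable near junctions for
  spacings much coarser than 1 µm.

## Command-line interface

The `dendrepair` script (in `exec/`) exposes `repair`, `cut`,
`experiment`, `stats`, `compare`, `synth` and `rin` subcommands over the
same functions, with a YAML config file whose values are overridden by
flags (YAML rather than TOML because this stack ships a YAML parser);
every run logs the effective parameters and seed to stderr and exits
non-zero on error.

## Reproduction script

`scripts/acceptance.R` re-runs the package's headline computations from
scratch — the MST equivalence check, the bf trade-off and recovery
experiments, branch-point matching, the 20-reference cut-and-repair suite
with its morphometric and input-resistance comparisons, the 200-trial
lesion experiment and the cable-theory validation — and writes the
resulting numbers to JSON. Problem sizes match the study conditions above;
with them the script completes in a few minutes on one CPU.
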