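# dendrepair

Repair of incomplete neuronal dendrite reconstructions by optimal-wiring
growth.

Most digital reconstructions of neurons are truncated — by the slice, the
imaging volume, or the tracer — and truncated dendrites corrupt every
statistic computed from them, from branch counts and Sholl profiles to
simulated excitability. `dendrepair` completes such reconstructions: it
grows synthetic dendrite into a user-specified 2D/3D region of an SWC
morphology, respecting the wiring economics that shape real dendrites, and
provides the tooling to validate the repair morphometrically and
electrotonically. It is aimed at neuroanatomists curating reconstruction
datasets and at modellers who need complete morphologies for compartmental
simulation.

## The model

Target points distributed in a growth volume $V$ are connected one at a
time to the existing tree, each time choosing the (target, node) pair that
minimises

```
total cost = wiring cost + bf · path-length cost
           =     d       + bf · (PL(node) + d)
```

with `d` the Euclidean span of the new connection and `PL` the path length
to the soma. The balancing factor `bf ∈ [0, 1]` is the single free
parameter of the growth rule: `bf = 0` minimises total cable (the rule is
then exactly Prim's minimum-spanning-tree algorithm), `bf = 1` minimises
conduction paths. Every other quantity a repair needs is estimated from
the input neuron itself: `bf` from the root-angle distribution, the
maximum span `G_thr` of a single connection from the chord of the
root-through-volume line, the target-point count from the branch-point
density, diameters from a fitted quadratic taper, roughness from the
input's tortuosity. Growth can sprout anywhere near the volume
("biological" mode) or exclusively from flagged incomplete terminals
("conserved" mode), and can match the branch-point count of a reference
morphology. In-silico dendriotomy (`random_cut()`,
`run_lesion_experiment()`) quantifies regeneration from the severed stem
versus invasion from neighbouring branches, and a steady-state passive
compartmental solver (`input_resistance()`) checks that a repair reverses
the input-resistance increase a lesion causes.

## Worked example

```r
library(dendrepair)

demo <- make_demo_2d()          # miniature planar tree, 2 flagged cut ends
demo$tree
#> <morph_tree> 12 nodes, 3 branch points, 4 terminals
#>   total cable length 144.61 um; labels: basal, soma
#>   cut-flagged terminals: 7, 12

vol <- growth_volume(cbind(c(45, 95, 45, 95), c(-45, -45, 30, 30)))
rep <- fix_tree(demo$tree, vol,
                growth_params(mode = "conserved", bf = 0.3, npts = 40,
                              seed = 1))
rep
#> <dendrite_repair> conserved growth, bf = 0.30, G_thr = 52.5 um
#>   40 new nodes (222.1 um of new cable), 0 unreachable targets
#>   branch points 3 -> 13; total length 144.6 -> 366.7 um

branch_stats(rep$tree)
#> <morpho_stats> NBr = 13, terminals = 14, total length 366.7 um,
#>   mean segment length 14.10 um over 26 segments

input_resistance(demo$tree)   # 1617.74 MOhm  (truncated: overexcitable)
input_resistance(rep$tree)    #  836.22 MOhm  (repaired: shunt restored)

write_swc(rep$tree, "repaired.swc")
```

The repair grew 222 µm of new dendrite from the flagged cut terminal into
the requested region, raised the branch-point count from 3 to 13, and cut
the somatic input resistance roughly in half — the direction a real
repair must move a lesioned, hyperexcitable cell. `plot(rep)` draws the
tree with new material in green. The same operations are scriptable via
the `exec/dendrepair` command-line tool (`repair`, `cut`, `experiment`,
`stats`, `compare`, `synth`, `rin`).

## Package layout

| Area | Contents |
| --- | --- |
| `R/morph_tree.R`, `R/swc.R` | morphology container, SWC I/O, resampling, tree surgery |
| `R/morphometry.R` | branch statistics, Sholl, root angles, RMSE%, discrete Fréchet |
| `R/geometry.R`, `R/growth_volume.R` | Delaunay/alpha-complex growth volumes, containment, chords |
| `R/mst_growth.R` | the optimal-wiring growth rule |
| `R/repair.R` | parameter estimation and the `fix_tree()` pipeline |
| `R/lesion.R` | dendriotomy and regeneration-vs-invasion experiments |
| `R/ephys.R` | steady-state passive input resistance |
| `R/synth.R` | synthetic arbour generators (all fixtures are code) |
| `exec/dendrepair` | command-line interface |
| `vignettes/` | methods vignette: model, parameters, design decisions |
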