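Package: dendrepair
Title: Optimal-Wiring Repair of Incomplete Neuronal Dendrite Reconstructions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Grows synthetic dendritic branches into user-specified volumes of
    incomplete neuronal reconstructions (SWC format) using a greedy optimal-wiring
    rule that balances total cable length against path length to the soma via a
    single balancing factor. Provides in-silico dendriotomy (random subtree cuts),
    regeneration-versus-invasion analysis, morphometric validation (branch
    statistics, Sholl analysis, discrete Frechet distance), automatic estimation
    of growth parameters (balancing factor from the root-angle distribution,
    target-point counts from branch-point density, growth threshold from the
    growth-volume chord), post-processing (spatial jitter, quadratic diameter
    taper, pruning), and a steady-state passive compartmental model for
    input-resistance checks of functional restoration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    Matrix,
    deldir,
    sp,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
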