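Package: mmiswitch
Title: Bistable Switches from Elementary mRNA-miRNA Reaction Circuits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mass-action models of an mRNA carrying one to three binding sites
    for a cognate miRNA, reduced under the total quasi-steady-state assumption
    to two slow variables (total mRNA and total miRNA) coupled through an
    algebraic binding equilibrium. The package locates steady states, labels
    their stability, traces one-parameter bifurcation diagrams with saddle-node
    folds, screens random kinetic parameter sets for bistability, verifies the
    analytic degradation-ratio condition for the two-site circuit, computes
    chemical-reaction-network structural indices (deficiency, linkage classes,
    weak reversibility), enumerates multi-site target motifs from miRNA
    target-site catalogs, and simulates rostrocaudal Hoxa5/Hoxc8 motor-neuron
    boundary formation on a cell grid under transient, noisy antiparallel
    retinoic-acid and FGF gradients, including miRNA-knockout and hysteresis
    protocols.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    deSolve,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
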