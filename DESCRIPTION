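Package: condnet
Title: Interaction-Network Microstructure Analysis of Biomolecular Condensates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize the internal microstructure of biomolecular
    condensates formed by sticker-spacer polymers such as prion-like
    low-complexity domains (LCDs). From residue sequences and bead-resolution
    configurations the package evaluates a residue-level coarse-grained
    (Mpipi-style) potential, builds energy-thresholded chain-chain interaction
    graphs, and quantifies small-world network statistics (sigma and omega
    estimators against Erdos-Renyi and latticized references), betweenness-
    centrality hubs and maximal cliques, radial density profiles with sigmoid
    interface fits, hub/clique spatial distributions and role lifetimes,
    single-chain gyration-tensor shape metrics and centrality power-law fits,
    surface tension by the Kirkwood-Buff and stress-profile routes,
    coexistence-density critical-point fits, and effective packing densities.
    A synthetic-data module generates droplet and slab configurations, short
    Langevin trajectories, and reference graph families so the full pipeline
    runs at desk scale without external trajectory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    minpack.lm,
    seqinr,
    stats,
    utils,
    yaml
Suggests:
    withr,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
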