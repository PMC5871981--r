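Package: SFBench
Title: Similarity-Aware Benchmarking of Protein-Ligand Scoring Functions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to study how protein similarity between training and test
    complexes shapes the accuracy of binding-affinity scoring functions.
    Parses protein (PDB) and ligand (SDF) structures into a heavy-atom model,
    computes intermolecular atom-pair count descriptors, AutoDock-Vina-style
    empirical terms and a four-term X-Score-like surrogate, builds nested
    training sets from a train-by-test protein-similarity matrix under an
    ascending cutoff schedule, fits deterministic multiple linear regression
    and stochastic random-forest scoring functions under a repeated-seed
    protocol, and summarises test-set Pearson correlation into learning
    curves. A synthetic-complex generator with clustered protein families
    provides complete desk-scale benchmarks so the whole analysis runs
    without external structural databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    ranger,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    bio3d,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
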