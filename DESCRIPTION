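Package: dtafuse
Title: Drug-Target Binding Affinity Regression with Fused Sequence and Graph Channels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts real-valued drug-target binding affinity (pKd, KIBA
    score) from a compound SMILES string and a protein amino-acid sequence.
    Three channels are fused: a SMILES-sequence channel and a protein-sequence
    channel, each a stack of 1D convolutions with squeeze-and-excitation
    channel attention, and a drug-graph channel encoded by a graph isomorphism
    network. Drug-protein interaction is modelled by two cross-multi-head
    attention blocks whose maps are decoupled into drug and protein position
    weights and fused into an interaction vector regressed by a multilayer
    perceptron. Includes the standard evaluation metrics of the field
    (MSE, concordance index, rm-squared, Pearson), a seeded synthetic-data
    generator with a planted pharmacophore-motif interaction, and
    gradient-weighted atom attribution (Grad-AAM) heatmaps. All network
    forward and backward passes are implemented in R and verified against
    finite-difference gradients.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    readr,
    jsonlite,
    yaml,
    Matrix,
    ChemmineR,
    withr
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    optparse
Config/testthat/edition: 3
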