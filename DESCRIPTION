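Package: GraphPLI
Title: Graph Neural Networks for Protein-Ligand Inhibitor Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Graph-based classification of small-molecule enzyme inhibitors,
    built around acetylcholinesterase screening. Small molecules parsed from
    SMILES become atom graphs with a 105-dimensional atom encoding; protein
    structures become residue contact-map graphs with a 24-dimensional residue
    encoding. A dilated-neighborhood GraphSAGE encoder, a scaled dot-product
    multi-head graph attention encoder, bidirectional cross-attention fusion
    and a multilayer-perceptron head are implemented with exact reverse-mode
    gradients and an Adam training loop. Includes a medicinal-chemistry
    curation pipeline (normalization, inorganic removal, Lipinski, Veber and
    PAINS filters), dataset labeling, balancing and splitting utilities, a
    virtual screening interface, and deterministic synthetic fixture
    generators.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    igraph,
    bio3d,
    ChemmineR,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
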