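Package: molbert
Title: Molecular BERT-Style Encoder with Chemistry- and Geometry-Biased
    Self-Attention
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A desk-scale molecular representation learner: SMILES strings
    are tokenized into paired atom and NMR-shift sequences with a global
    node, and encoded by a transformer whose self-attention is gated by the
    molecular adjacency, biased by normalised bond dissociation energies,
    and shifted by a learned transformation of the interatomic distance
    matrix.  Pre-training combines masked atom and NMR-token reconstruction,
    bond-energy regression and 3D geometry reconstruction (distances, bond
    angles, torsions) under an uncertainty-weighted multi-task loss;
    fine-tuning attaches a small head to the global-node representation for
    property prediction with scaffold-split evaluation.  Includes a seeded
    deterministic conformer embedder, surrogate NMR/bond-energy lookup
    tables with a user-override interface, a synthetic fixture generator
    with a closed-form label, attention-map interpretability exports, and a
    reverse-mode automatic differentiation engine the training loops run on.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    ChemmineR,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    yaml
Config/testthat/edition: 3
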