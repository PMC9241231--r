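Package: deepPN
Title: Parallel Convolutional and Chebyshev Graph-Convolutional Networks
    for RNA-Binding Protein Site Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts whether a fixed-length RNA window contains an
    RNA-binding-protein (RBP) binding site using a two-branch neural
    classifier: a motif-scanning convolutional branch and a spectral
    graph-convolutional (ChebNet) branch over the sequence-position
    graph, fused by a fully connected head. Includes one-hot and k-gram
    sequence encoders, a scaled-Laplacian/Chebyshev-polynomial toolkit,
    deterministic mini-batch training with Adam and early stopping, and
    a synthetic planted-motif generator emulating CLIP-seq
    positive/negative datasets for desk-scale benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
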