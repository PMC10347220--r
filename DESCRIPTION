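Package: scanfuse
Title: Multimodal Fusion of CT Slice Stacks and Clinical Indicators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scan-level binary diagnosis from a variable-length stack of CT
    slice images together with a fixed-length vector of clinical indicators.
    Implements grouped uniform-random slice sampling, a hierarchical
    transformer image encoder with Unidirectional Selective Attention (the
    indicator feature queries the slice features, never the reverse), and a
    graph-convolutional feature-fusion head that coarsens the slice-feature
    graph with a max-score feature sampling algorithm. Training uses a joint
    diagnosis plus node-selection cross-entropy loss; forward and backward
    passes are computed by a compact reverse-mode automatic differentiation
    core included in the package. A synthetic phantom-scan generator makes
    the full pipeline testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    png,
    EBImage,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
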