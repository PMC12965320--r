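Package: gvbscreen
Title: High-Content Quantification of Granulovacuolar Degeneration Bodies in
    Neurons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Single-neuron quantification pipeline for high-content screening
    of granulovacuolar degeneration bodies (GVBs) in primary neuron cultures
    with tau pathology. Provides a synthetic multi-channel field generator
    with planted ground truth, DAPI/MAP2 nucleus and soma segmentation, a
    GVB punctum detection and cluster-acceptance cascade, GVB+/GVB- neuron
    classification, per-population intensity readouts with control-normalized
    well aggregation, an expected-versus-observed exponential half-life
    estimator for the GVB+ neuron population, and nested replicate statistics
    (nested t test, nested one-way ANOVA with Dunnett or Sidak post hocs,
    paired t test, robust outlier flagging).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    stats,
    utils,
    tiff,
    multcomp
Suggests:
    testthat (>= 3.0.0),
    lmerTest,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
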