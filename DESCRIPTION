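Package: simsDiff
Title: Differential Analysis of ToF-SIMS Imaging Studies
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: End-to-end analysis of Time-of-Flight Secondary Ion Mass
    Spectrometry (ToF-SIMS) imaging studies with a multi-group design:
    simulation of synthetic studies with realistic counting noise, imzML
    input/output, mass-axis calibration against reference ions, central
    region-of-interest extraction, peak integration, total-ion-count
    normalisation, replicate aggregation, per-ion one-way ANOVA with
    Tukey-Kramer post hoc contrasts and Benjamini-Hochberg FDR control,
    trend classification and recovery-index quantification of treatment
    effects, class-level contribution summaries, and reporting surfaces
    (volcano data, Z-score hierarchical clustering, boxplot summaries and
    fixed-scale ion maps).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment,
    xml2,
    yaml,
    car
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
biocViews: MassSpectrometry, ImagingMassSpectrometry, Lipidomics,
    Metabolomics, DifferentialExpression, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
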