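Package: realcsf
Title: Aneuploidy and Focal Amplification Calling for CSF Liquid Biopsies
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects central nervous system cancers from shallow
    repetitive-element amplicon sequencing of cerebrospinal fluid DNA.
    Read counts are aggregated onto a fixed-width autosomal interval grid,
    normalized against a euploid reference panel with PCA denoising,
    segmented per chromosome arm by circular binary segmentation, and
    summarized as arm-level Z statistics. A radial-kernel support vector
    machine converts the 39 arm scores into a Global Aneuploidy Score,
    focal oncogene windows (MDM4, EGFR, CDK4, ERBB2) are scored by a
    Poisson Z test against panel expectation, and a Boolean OR gate
    produces the composite call. A synthetic-sample simulator with known
    truth makes every stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    e1071
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'genome-model.R'
    'counts-io.R'
    'reference-panel.R'
    'segmentation.R'
    'arm-scores.R'
    'gas-classifier.R'
    'focal-amplification.R'
    'composite-report.R'
    'synthetic-data.R'
    'utils.R'
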