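Package: dmsfunc
Title: Functional Scoring and Variant Classification for Deep Mutational
    Scanning Screens
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis of pooled deep mutational scanning (DMS) proliferation
    screens at codon resolution: enumeration of codon-level variant libraries
    over an open reading frame, per-replicate log2 fold changes of variant
    abundance, rolling silent-codon baselines, per-variant functional z-scores
    aggregated across replicates, loss-of-function calling and residue
    intolerance ranking, benchmarking against computational variant-effect
    predictors (threshold concordance, ROC/AUC), a Fisher exact quadrant
    concordance statistic for paired accessibility/expression fold changes,
    and a fully seeded synthetic screen generator with known ground truth for
    validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    withr
biocViews: Software, FunctionalGenomics, PooledScreens, StatisticalMethod
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'classification.R'
    'dmsfunc-package.R'
    'genetic-code.R'
    'io.R'
    'library.R'
    'multiomic.R'
    'predictor-eval.R'
    'scoring.R'
    'simulate.R'
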