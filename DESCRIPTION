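Package: vocims
Title: GC-IMS Fecal Volatolomics for Disease-Course Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for gas chromatography-ion mobility
    spectrometry (GC-IMS) volatile organic compound profiles of fecal
    samples in inflammatory bowel disease. Provides S4 containers and an
    open interchange format for 2-D GC-IMS intensity matrices, a synthetic
    cohort generator with planted discriminatory peaks, crop-and-threshold
    preprocessing, disease-activity state labelling (fecal calprotectin,
    Harvey Bradshaw Index, Simple Clinical Colitis Activity Index) with
    longitudinal sample pairing into transition groups, leakage-safe
    cross-validated Wilcoxon rank-sum feature selection with support vector
    machine and random forest classification, and ROC-based evaluation
    (AUC with DeLong confidence intervals, Youden-optimal cut-off metrics).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    jsonlite,
    data.table,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'AllClasses.R'
    'AllGenerics.R'
    'io.R'
    'synthetic.R'
    'preprocess.R'
    'disease-state.R'
    'wilcoxon.R'
    'classifiers.R'
    'modelling.R'
    'evaluation.R'
    'pipeline.R'
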