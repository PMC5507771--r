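Package: metaboPredict
Title: Prodromal Metabotype Modelling for Urinary 1H-NMR Cohorts
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for pharmaco-metabonomic prediction of dietary-challenge
    outcomes from pre-intervention urinary 1H-NMR metabotypes. Implements
    spectral simulation of an isogenic-mouse cohort with planted
    metabolite-outcome couplings, recursive segment-wise peak alignment,
    probabilistic quotient normalization, statistical recoupling of
    variables (SRV) feature extraction, O-PLS(-DA) with k-fold
    cross-validated Q2, permutation-based empirical p-values, ROC analysis
    of cross-validated scores, Spearman permutation association mapping
    between baseline metabolites and late phenotypes, and 2-SD phenotype
    stratification into disease sub-groups.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
biocViews: Metabolomics, Classification, Regression, Preprocessing
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'SpectralSet.R'
    'association.R'
    'metaboPredict-package.R'
    'metaboliteLibrary.R'
    'opls.R'
    'pipeline.R'
    'preprocess.R'
    'simulateCohort.R'
    'srv.R'
    'stratify.R'
    'synthesizeSpectrum.R'
    'utils.R'
    'validation.R'
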