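Package: petstage
Title: Whole-Body PET/CT Uptake Classification and Automated miTNM Staging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing paired whole-body PET/CT volumes in prostate
    cancer imaging. Candidate uptake regions are segmented by incremental
    connected-component extraction with per-region 45%-of-SUVmax thresholding,
    represented as thirteen two-channel coronal multiplanar reformations, and
    classified by a compact multi-task convolutional network (suspicious
    vs. nonsuspicious uptake plus anatomical location), with dual-tracer
    training strategies including transfer learning and a tracer-type input
    bit. Anatomical locations of suspicious findings are mapped to PROMISE
    miTNM N and M stage categories. Includes the full evaluation toolkit
    (average precision, pooled and per-subject detection metrics,
    subject-level bootstrap confidence intervals, paired z-tests with
    Bonferroni correction, confusion matrices and percent agreement) and a
    synthetic dual-tracer phantom generator so every component is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    RNifti,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
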