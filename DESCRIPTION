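Package: ctquant
Title: Automated Atrophy and White-Matter-Lesion Grading from Head CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates medial temporal lobe atrophy (MTA), global cortical
    atrophy (GCA, whole brain and per lobe) and white-matter-lesion burden
    (Fazekas grade) from head CT volumes. The pipeline combines
    expectation-maximization skull stripping, affine registration of binary
    skull masks followed by normalized-mutual-information nonrigid
    refinement against a mean CT template, a small residual U-shaped
    convolutional network segmenting CSF and white-matter lesions with
    correlation-weighted ensemble fusion, and a two-step (linear plus
    piecewise-linear) calibration from normalized volumetric measures to
    ordinal grade scales. Also provides the agreement battery used to
    compare grade sources (Pearson correlation, identical and within-one
    grade percentages, quadratically weighted Cohen's kappa, Bland-Altman
    limits of agreement) and a synthetic head-phantom generator with known
    severity parameters for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
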