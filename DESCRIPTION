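Package: fissuremap
Title: Texture-Based Detection and Occlusion Localization of Annular Fissures in Disc MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Non-invasive detection of outer annular fissures of the
    intervertebral disc from midsagittal T2-weighted magnetic resonance
    images. Implements an IBSI-style texture-feature engine (grey-level
    co-occurrence, neighbourhood grey tone difference and grey-level
    dependence matrices, spatial autocorrelation and first-order
    statistics), an ensemble of shallow feed-forward neural networks
    trained with momentum and adaptive learning rate under patient-level
    stratified cross-validation, an occlusion-based attention-mapping
    algorithm that localizes the fissure within the disc, and diagnostic
    test statistics (sensitivity, specificity, likelihood ratios, ROC and
    the mid-p McNemar test). A synthetic disc-phantom generator provides
    fully reproducible cohorts with ground-truth fissure masks for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    pROC,
    RNifti,
    rlang
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
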