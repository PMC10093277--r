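Package: petuq
Title: Uncertainty-Aware PET/CT Lesion Segmentation Evaluation and
    Radiomics Survival Analysis
Version: 0.1.0
Authors@R:
    person("petuq", "developers", email = "petuq@example.org",
           role = c("aut", "cre"))
Description: Desk-scale toolkit for uncertainty-aware evaluation of head and
    neck PET/CT lesion segmentation and downstream survival modelling.
    Provides synthetic PET/CT phantoms with multi-lesion ground truth,
    checkpoint-ensemble simulation, a toy 3D U-Net with residual blocks,
    squeeze-and-excitation and grid attention trained under a cyclic
    learning-rate schedule with posterior checkpoint sampling, ensemble
    variance uncertainty maps, lesion-level uncertainty density and
    false-positive reduction sweeps, aggregated Dice and detection metrics,
    multi-region multi-modal radiomics feature extraction, two-step
    concordance-based feature selection with a boosted Cox survival learner,
    tertile risk stratification with Kaplan-Meier and log-rank analysis, and
    a subgroup fairness and Shapley explainability harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    survival
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
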