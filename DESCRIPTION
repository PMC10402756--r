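Package: dctrunet
Title: Dilated-Convolution Transformer Residual U-Nets for 2D Tumor
    Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds, trains and evaluates DCTR U-Net segmentation
    networks: U-shaped encoder-decoder models whose per-stage blocks
    combine dilated convolutions, pre-norm transformer layers and
    residual connections, targeted at single-channel 2D medical images
    such as nasopharyngeal-carcinoma MR slices.  Includes the baseline
    U-Net and the two single-module ablation variants behind one
    factory, Dice and average-symmetric-surface-distance (ASSD)
    evaluation with physical pixel spacing, an MRI-like phantom cohort
    generator with per-patient grouping, patient-level k-fold
    cross-validation, and a command-line interface for reproducible
    generate/train/evaluate/ablate runs.  All network layers carry
    hand-derived reverse-mode gradients backed by compiled kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    png,
    RNifti,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
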