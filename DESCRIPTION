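Package: ieegloc
Title: Semi-Automatic Localization, Numbering and Labeling of
    Intracranial EEG Electrodes from CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Locates intracranial EEG electrode contacts (subdural grids,
    strips and depth arrays) from a co-registered post-implantation CT
    volume and a brain mask. Electrode artifacts are isolated by
    morphological mask adjustment and Hounsfield thresholding, clustered
    with K-means, and localized as intensity-weighted centers of mass.
    Depth arrays are numbered along their principal axis and grids by a
    convex-hull corner / ideal-grid / permutation-refinement procedure.
    Contacts can be labeled from a 4D probabilistic atlas, and grids
    projected to a smoothed cortical envelope by constrained energy
    minimization with a Gaussian displacement field propagated to depth
    electrodes to correct brain shift. Includes a synthetic CT phantom
    generator with known ground truth, inter-rater reliability statistics
    (Krippendorff's interval alpha), and a paired sign-flip permutation
    test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    readr,
    Matrix,
    igraph,
    jsonlite,
    yaml,
    withr,
    generics,
    ggplot2,
    stats,
    grDevices,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
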