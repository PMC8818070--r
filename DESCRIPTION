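Package: fetmirror
Title: Mirror-Image Background Definition and Biological Tumour Volume
    Delineation for Amino-Acid PET
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Semiautomated delineation of biological tumour volume (BTV) in
    brain-extracted 18F-FET PET images. Implements the iterative mirror-image
    (MI) method, in which the background reference region is generated
    automatically as the contralateral reflection of the tumour segmentation
    and refined to convergence, and the guided crescent-shape (gCS)
    comparator, in which a reader-drawn crescent VOI normalises the image in
    a single pass. Includes seeded 3D threshold-connected region growing,
    tumour-to-brain-ratio normalisation, a synthetic brain-phantom and
    simulated-reader generator, and reader-reliability statistics
    (intra-/inter-reader coefficient of variation and ICC(2,1) with
    confidence intervals).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    RNifti,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
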