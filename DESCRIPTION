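Package: myelinquant
Title: High-Throughput Quantification of Oligodendrocyte Ensheathment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies myelin-like ensheathment formed by oligodendrocytes
    cultured on aligned electrospun nanofibers, from multi-channel
    fluorescence well images. Provides two segmentation engines: a heuristic
    two-stream pipeline (CLAHE contrast enhancement, Hessian ridge filtering
    of ensheathed fiber segments, watershed cell-body estimation with imposed
    distance maxima, cell-body subtraction and continuity-based per-cell
    association) and a compact UNet trained on masked-nucleus crops with
    class- and spatially-weighted per-pixel cross-entropy. Includes the
    post-inference operators (unfair distribution of shared sheaths,
    skeleton-based removal of sticky cross-fiber bridges, two-pass minimum
    length filtering), per-cell morphometrics (sheath counts, ellipse-based
    lengths, mean sheath length per cell, Jaccard evaluation) and power
    calculations, plus a seeded phantom generator that renders synthetic
    nanofiber cultures with exact per-cell ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
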