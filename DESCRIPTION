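Package: xenotrack
Title: Simulation and Quantification of Tumor Cell Dissemination in
    Embryonic Zebrafish Xenografts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An agent-based simulator and analysis pipeline for time-lapse
    light-sheet movies of human tumor cells xenografted into embryonic
    zebrafish. Builds a stylized 2D embryo atlas (vasculature, caudal
    hematopoietic tissue, avascular fin folds, flow field), simulates
    cell-type-specific intravascular dissemination with ground truth,
    renders multi-channel movies, segments and links cells into tracks
    (Hungarian assignment with gap closing and a replayable edit log),
    computes per-cell dissemination metrics (maximum, net and total
    distance, speed), scores invasion, macrophage colocalization and
    survival phenotypes per embryo, and runs the nonparametric group
    statistics battery with significance star coding.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    multcomp,
    Rcpp,
    stats,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
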