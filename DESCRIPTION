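Package: stallox
Title: Capillary Stall and Oxygen Dynamics from Two-Photon Phosphorescence Lifetime Point Measurements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for two-photon phosphorescence lifetime (2PLM)
    point measurements of capillary oxygen in the brain: pooling photon-count
    cycles into decay histograms, single-exponential lifetime fitting with a
    Poisson likelihood, Stern-Volmer conversion to pO2, red-blood-cell flux and
    speed from dye-exclusion intensity dips via Otsu binarization, tissue-pO2
    estimation from the erythrocyte-associated transient (EAT), detection and
    characterization of capillary stall events (hypoxia classification,
    peri-stall alignment, neighbor effects), and vessel-density geometry from
    3D angiogram volumes. Includes a synthetic-data generator providing ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    tiff,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
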