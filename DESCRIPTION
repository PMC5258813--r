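Package: colonycyto
Title: Imaging Cytometry of Pluripotent Stem-Cell Colonies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of imaging-cytometry experiments on
    human pluripotent stem-cell colonies. Generates synthetic multi-channel
    fluorescence fields of tightly packed colony nuclei with known per-cell
    ground truth, segments nuclei with a distance-transform watershed,
    quantifies per-nucleus marker intensities, gates cells against
    negative-control thresholds into quadrant expression profiles, compares
    imaging-derived percent-positive profiles with simulated flow-cytometry
    readings of the same population, and scores spatial edge enrichment of
    marker phenotypes within colonies with a permutation test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
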