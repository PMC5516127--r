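Package: synaptomo
Title: Array-Tomography Synapse Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies synapses in serial-section array-tomography
    fluorescence volumes: translation registration of 70 nm sections,
    combined Otsu/triangle thresholding so both bright and dim puncta are
    segmented, 3D connected-component reconstruction of synaptic puncta
    with a single-section noise filter, volume-overlap colocalization of
    tau with postsynaptic densities, detection of putative synaptic pairs
    by centroid proximity, and per-mouse aggregation with two-way ANOVA or
    Kruskal-Wallis group comparisons. A ground-truthed synthetic scene
    generator emulates punctate synaptic immunoreactivity for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    broom,
    car,
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
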