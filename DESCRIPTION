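Package: slicetrack
Title: Multiple Particle Tracking and Viability Analysis for Brain Slice Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for nanoparticle multiple particle tracking (MPT)
    in the extracellular space of organotypic brain slices: time-averaged mean
    squared displacements, effective diffusion coefficients via the
    Einstein-Smoluchowski relation, anomalous diffusion exponents from log-log
    fits, and diffusion-mode classification with population summaries.
    Includes companion quantification for slice viability experiments
    (metabolic-activity normalization, cumulative LDH release, Otsu-based
    nuclei counting and marker-positive percentages, intensity ratios), a
    normality-gated statistical comparison decision tree, and synthetic-data
    generators (Brownian, fractional Brownian, immobile, directed and mixture
    trajectories; two-channel nuclei images; longitudinal plate-reader tables)
    so every stage is testable against known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    xml2,
    jsonlite,
    tiff,
    withr,
    igraph,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    car,
    EBImage
Config/testthat/edition: 3
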