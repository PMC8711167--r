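Package: strainscope
Title: Spectral Phenotyping of Amyloid Plaque Strains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for in-situ amyloid-beta strain analysis from
    conformation-sensitive fluorescent dye spectra. Builds per-plaque
    composite spectral vectors from three-dye emission spectra (grid
    alignment, per-dye max-normalization, concatenation, per-patient
    subsampling), fits a PCA strain space, classifies plaques against
    kernel-density coverage regions of reference cohorts, quantifies
    per-patient and per-cohort strain heterogeneity with a
    variance-weighted RMSD statistic, and performs cohort-level inference
    (Wilks' lambda MANOVA, centroid-covariate regression, rank tests).
    Includes plaque segmentation from spectral lambda-stack images,
    semiquantitative neuropathology scoring from plaque and tangle
    densities, and a synthetic-data generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
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
    stats,
    utils,
    tools,
    ggplot2,
    generics,
    jsonlite,
    readr,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
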