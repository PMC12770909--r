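Package: dstacs
Title: Electric-Field Metrics for Dual-Site Transcranial Alternating
    Current Stimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reconstructs phase-lagged dual-site transcranial alternating
    current stimulation (ds-tACS) electric fields on cortical surface
    meshes by linear superposition of three basis fields, and quantifies
    how the field depends on the phase lag between the two stimulation
    sites. Implements peak magnitude and cortex-normal peak metrics, the
    relative difference measure (RDM) of spatial redistribution, the
    normal-component dot product and its deviation from the ideal
    separated-field value, and the effective area of stimulation; tests
    phase-lag modulation with a weighted Hermans-Rasson permutation test
    with Bonferroni-Holm correction; quantifies inter-individual
    variability by coefficients of variation; and selects individualized
    montages from a candidate set. Ships a synthetic cortical-sheet and
    basis-field generator so the whole pipeline runs without MRI-derived
    head models or finite-element solves.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
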