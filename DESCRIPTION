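Package: perturbstress
Title: Stress-Pathway Gene-Set Profiling for Pseudobulk Perturb-seq Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Profiles the activation of stress-responsive signaling pathways
    (integrated stress response, unfolded protein response and its ATF6 and
    IRE1/XBP1s arms, heat shock response, oxidative stress response) in
    pseudobulk CRISPRi Perturb-seq z-score data. Computes per-perturbation
    pathway activation scores (mean z-score of curated target-gene panels),
    tests them against a stable control gene set with Welch and
    Brown-Forsythe statistics, performs perturbation-pair transcriptome
    regression with |z| filtering, gene-class (mtDNA) contrasts and
    principal component analysis, and ships a fully deterministic synthetic
    pseudobulk generator with per-gemgroup control-based z-normalization
    and ground-truth tables for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    car,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    rhdf5
Config/testthat/edition: 3
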