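Package: rpeclamp
Title: Whole-Cell Potassium Current Simulation and Patch-Clamp Analysis for
    Retinal Pigment Epithelium
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward simulation of heterogeneous whole-cell K+ channel
    populations of retinal pigment epithelial cells (delayed rectifier,
    M-current, A-type and mildly inward-rectifying Kir7.1 phenotypes) under
    episodic voltage-clamp protocols, together with the analysis pipeline
    used to characterise such recordings: liquid-junction-potential
    corrected current-voltage curves, tail-current conductance extraction
    with Boltzmann activation fits (V1/2, slope, gmax), per-cell phenotype
    classification, pharmacological block quantification, and cohort
    statistics (incidence, mean +/- SEM, exact Mann-Whitney U).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
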