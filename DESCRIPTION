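Package: fpscreen
Title: Fluorescence Polarization Screening and Hit Characterization for
    Allosteric Kinase Modulators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for a fluorescence-polarization (FP)
    competition screen against the regulatory (Ncap-SH3-SH2-linker) region
    of the ABL tyrosine kinase, and for the orthogonal assays used to
    characterize confirmed hits.  Implements plate-level quality control
    (Z-factor), normalized percent inhibition and Z-score compound scoring,
    the three-ranking hit-selection rule with retest confirmation and a
    fluorescence-quencher counter-screen, Boltzmann thermal-shift (DSF) Tm
    estimation, global 1:1 Langmuir kinetic fitting of SPR sensorgrams, and
    ADP-based kinase progress-curve reduction with Michaelis-Menten,
    activator-saturation (K_act) and EC50 fitting.  A seeded synthetic-data
    module generates every input the pipeline consumes with the statistical
    structure of the original screen.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
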