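Package: tcellpbmc
Title: Quantitative Analysis of T Cell:PBMC Immunogenicity Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of in vitro CD4+ T cell:PBMC assays used to assess the
    immunogenicity potential of biopharmaceuticals. Takes well-level
    proliferation (counts per minute of 3H-thymidine incorporation) and IL-2
    ELISpot (spots per well) measurements and computes stimulation indices,
    dual-criterion (SI > 2 and p < 0.05) responder calls per readout, donor
    level responder classification, Poisson limiting-dilution estimates of the
    antigen-specific CD4+ T cell precursor frequency, cohort-level
    immunogenicity summaries, and HLA-DRB1 allele-frequency comparisons
    against reference populations. Includes a generative model of the assay
    for calibration, power studies and end-to-end pipeline validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
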