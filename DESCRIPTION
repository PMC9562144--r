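Package: octadrive
Title: Octad Dissection Analysis of Killer Meiotic Drivers in Fission Yeast
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting and modelling spore-killing meiotic drive
    from octad dissection data of eight-spored fission yeasts such as
    Schizosaccharomyces octosporus. Provides validation, filtering and
    octad-type classification of dissection tables; exact binomial and
    Fisher's exact tests with the conventions used in classical spore
    viability analysis; transmission distortion statistics and driver
    classification rules; a generative poison/antidote spore-killing model
    with maximum-likelihood parameter estimation, bootstrap intervals and
    power analysis; calibration of motif-scan p-value cutoffs and
    gene-level motif enrichment statistics for FIMO-style hit tables; and
    reproducible synthetic-data generators for every input the pipeline
    consumes.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
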