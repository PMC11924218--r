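Package: marinp
Title: Classical Nucleation Theory Modelling of Marine Polysaccharide
    Ice-Nucleating Macromolecules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing droplet freezing assays of marine
    ice-nucleating macromolecules (INMs) and for modelling the resulting
    ice-nucleating particle (INP) populations. Converts per-droplet freezing
    records into cumulative Vali spectra with exact binomial confidence
    bounds, normalises site densities to chemical measures such as
    carbohydrate carbon (C-TCCHO), and fits a classical nucleation theory
    (CNT) model with a truncated-normal contact-angle distribution by
    maximum likelihood. Fitted parametrizations, together with dust and
    sea-spray surface-site-density schemes, are applied to gridded aerosol
    fields to map INP concentrations and the polysaccharide share of the
    INP population, and are evaluated against observation records with
    factor-of-2/factor-of-10 agreement metrics and an improvement fraction.
    A seeded synthetic-data generator emulates every input so the whole
    pipeline runs end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    pracma,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    jsonlite,
    withr
Config/testthat/edition: 3
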