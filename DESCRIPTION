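Package: cntrelease
Title: Drug-Release Kinetics and Carbon-Nanotube Adsorption Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing drug release from carbon-nanotube carriers.
    Fits seven classical dissolution models (zero-, first- and second-order,
    Higuchi, Hixson-Crowell, Weibull, Korsmeyer-Peppas power law) to
    cumulative release time courses, ranks them by the coefficient of
    determination and classifies the transport mechanism from the power-law
    exponent n or the Weibull shape b. A companion arm computes configuration
    statistics for nanotube/ligand coordinate snapshots in periodic boxes:
    single-linkage aggregate detection under the minimum-image convention,
    adsorbed fractions, and a ring/virtual-sphere algorithm that counts
    ligands encapsulated inside the nanotube. A synthetic-data generator
    produces release curves and boxed configurations with exact ground truth
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
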