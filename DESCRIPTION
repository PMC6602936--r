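Package: resistkit
Title: Individual-Based Landscape Genetics with Circuit-Theory Resistance Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An individual-based landscape-genetics inference chain for
    microsatellite data: per-locus diversity and null-allele screening,
    shared-allele (Dps) genetic distances, multivariate spatial
    autocorrelation correlograms, circuit-theory effective resistance and
    cumulative current maps on raster resistance surfaces, Mantel and
    partial Mantel tests with permutation inference, multiple regression
    on distance matrices with AICc model selection, and the causal-modelling
    procedure that selects optimized resistance surfaces against an
    isolation-by-resistance null. Includes a stepping-stone Wright-Fisher
    simulator with stepwise microsatellite mutation for generating
    landscapes and genotypes with known resistance structure, so the whole
    chain is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    vegan,
    jsonlite
Config/testthat/edition: 3
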