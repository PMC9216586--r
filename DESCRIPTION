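Package: ssforge
Title: Stereochemical Modelling and Search of Protein Disulphide Bridges
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Toolkit for disulphide bond engineering and modelling in
    protein structures. Identifies residue pairs that can strainlessly
    accommodate an engineered disulphide bridge by CA/CB distance
    screening, fixes sulphur atoms geometrically with an exhaustive chi1
    rotamer grid search, and grades each site A-D by stereochemical
    quality. Generates random Ramachandran-allowed backbone conformations
    for disulphide-rich peptides under connectivity constraints, with
    optional secondary-structure clues. Builds a searchable database of
    disulphide-bonded loop segments queryable by multi-disulphide
    connectivity pattern, with loop topology classification and
    sequence-identity ranking. Includes deterministic synthetic fixtures
    with exactly known bridge geometry and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
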