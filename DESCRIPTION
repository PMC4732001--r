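Package: fragrank
Title: In Silico Fragmentation and Evidence-Weighted Ranking of Candidate
    Structures from Tandem Mass Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies small molecules from high-resolution tandem mass
    spectra by combinatorial bond-dissociation fragmentation of candidate
    structures retrieved from a local compound database, peak matching under
    additive ppm/Da tolerances, and a weighted combination of fragmentation,
    retention-time, reference-count, substructure and suspect-list evidence.
    Includes candidate filters (unconnected structures, element restrictions,
    SMARTS substructures, suspect inclusion), InChIKey-based stereoisomer
    deduplication, ranking metrics (pessimistic and expected ranks, relative
    ranking position), weight-simplex exploration, and a synthetic-data
    generator for end-to-end validation without external databases.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    igraph,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
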