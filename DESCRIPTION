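Package: protrack
Title: Protein Production and Purification Tracking
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A laboratory information management toolkit for protein
    production and purification groups.  Tracks the full reagent lineage
    from expression construct through cell line and conditioned-media
    supernatant ("supe") to purified protein batch in an embedded SQLite
    store with referential integrity, search and pagination.  Computes
    sequence-derived properties at record submission (average molecular
    weight, 280 nm extinction coefficients for reduced and oxidized
    cysteines, 0.1% absorbance, N-linked glycosylation sequon count) and
    keeps batch mass bookkeeping current as aliquots are consumed.
    Includes a reagent-request workflow (Pending/Started/Fulfilled state
    machine with per-kind priority queues and pluggable notification
    sinks), chain-of-custody lineage reports, FASTA/CSV import/export, a
    deterministic synthetic-store generator, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    DBI,
    RSQLite,
    jsonlite,
    yaml,
    Biostrings,
    utils,
    stats
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
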