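Package: atlasscreen
Title: Consensus Screening of Highly Expressed Targets Against Background
    Expression Atlases
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Identifies genes or transcripts significantly more highly
    expressed in an input RNA-seq sample group than in every tissue or
    cell-type category of one or more background expression atlases, using
    a one-sided Welch test against the adversarial (highest-mean) category
    computed from compact per-category summary statistics. Significance
    calls are aggregated across many (group x background) comparisons into
    a consensus target set, which is then filtered by membrane/secreted
    protein membership, flagged for overlap with aged-tissue and disease
    gene sets, and characterised with local Fisher-exact gene-set
    enrichment. Includes a synthetic-data generator with planted
    over-expressed features for power and false-discovery evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
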