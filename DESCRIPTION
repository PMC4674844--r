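Package: AssocMiner
Title: Multi-Evidence Guilt-by-Association Gene Mining
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores the association between gene pairs under multiple kinds of
    biological evidence (shared transcription-factor binding and regulation,
    shared mutant phenotypes, functional annotations, literature links,
    physical and genetic interaction partners) using the upper tail of the
    hypergeometric distribution, imports precomputed expression-profile
    association scores, min-max normalizes the per-type scores for a query
    gene and sums the chosen types into an overall association score. Ranks
    candidate genes for a query, flags per-type evidence at a genome-wide
    percentile cutoff, exports confidence and evidence networks in SIF and
    GraphML form, and summarizes overlaps between top-k ranked lists obtained
    under different evidence selections. Includes a seeded synthetic-catalog
    generator with planted associations for validation without any database
    download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
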