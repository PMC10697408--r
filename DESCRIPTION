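Package: nukasv
Title: Shared-ASV Source Tracking for Paired Fermented-Food and Skin Microbiomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for tracking bacterial transmission from a fermented
    rice-bran bed (Nukadoko) to human palm skin with paired 16S rRNA
    amplicon samples. Implements feature-table, taxonomy and metadata
    input/output with validation; organelle and unassigned-ASV filtering
    with exact read accounting; genus-level composition summaries; alpha
    diversity (Shannon index, observed features) with exact
    without-replacement rarefaction curves; the dual-threshold shared-ASV
    statistic under same-day and fixed-source-day pairing schemes, with
    sink-side shared proportions, taxonomic breakdowns and persistence
    summaries; reference-sequence curation filters (degenerate-base and
    homopolymer culling, domain-conditional length filtering, uniq-mode
    dereplication); and a ground-truthed simulator of source-to-sink
    transfer with exponential shedding and multinomial read sampling, so
    the whole pipeline is testable without sequence downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse
Config/testthat/edition: 3
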