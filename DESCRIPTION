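Package: enhancerkit
Title: Tag-Based Quantification and Classification of Signal-Dependent
    Enhancers
Version: 0.1.0
Authors@R:
    person("enhancerkit", "developers", email = "enhancerkit@example.org",
           role = c("aut", "cre"))
Description: Desk-scale re-implementation of a ChIP-seq/CUT&RUN/PRO-seq tag
    analysis workflow for signal-dependent enhancers: HOMER-style tag
    directories (per-position clonal cap, normalization to 10 million tags),
    windowed and gene-body quantification, profile matrices, a Poisson
    local/global background peak caller with a replicate-concordance filter,
    the six tag-threshold enhancer-group definitions (MegaTrans, ER-alpha
    other-active, other-active, proinflammatory, androgen- and
    depolarization-induced), fold-change differential calls for eRNAs and
    gene bodies, interval overlap and random-background enrichment
    statistics, and a seeded synthetic-data generator with planted ground
    truth so the whole pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
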