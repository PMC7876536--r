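Package: holonet
Title: Transkingdom Co-Abundance Network Analysis for Holobiont Interaction Discovery
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers signed weighted co-abundance networks separately for a host
    transcriptome and a gut microbiota count table, summarizes network modules by
    eigennodes (module eigengenes / eigenOTUs), optionally removes permutation-validated
    large latent effects, and predicts putative host-microbiota interactions by
    correlating module eigennodes with each other and with encoded host traits in an
    integrated heatmap (iHAHI). Includes TMM and cumulative-sum-scaling normalization
    front ends, biweight midcorrelation, signed topological overlap, tree-cut module
    detection with KME-based trimming and eigennode merging, hypergeometric term
    enrichment, and a synthetic holobiont data generator with planted modules and
    cross-kingdom couplings for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    edgeR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    sva,
    pheatmap,
    optparse,
    withr
Config/testthat/edition: 3
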