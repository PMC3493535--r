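Package: epidrg
Title: Integrative Epigenetic and miRNA Characterization of Drought-Responsive Genes
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for characterizing drought stress-responsive
    genes (DRGs) by their epigenetic and small-RNA regulatory context. Maps DNA
    methylation read intervals onto genic spans and 1 kb promoter windows,
    attaches miRNA-target and chromatin-gene annotations, classifies DRGs into
    nine rule-based feature/direction clusters, and characterizes the clusters
    with Monte Carlo z-score enrichment against random-gene backgrounds, Fisher
    exact GO-term enrichment with Benjamini-Yekutieli correction, G-statistic
    contingency tests, transcription factor/protein domain/pathway
    distributions, protein-protein interaction degree summaries and four-set
    overlap counts. A synthetic-data generator produces complete input bundles
    with planted, configurable enrichments and recorded ground truth so the
    whole pipeline can be exercised and validated without external resources.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
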