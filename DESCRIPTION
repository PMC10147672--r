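Package: founderscape
Title: Founder-Population Structure and Ancestry from IBD Segment Sharing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying founder populations through identity-by-descent
    (IBD) segment sharing: a forward-in-time founder-colony simulator with
    recombination and full ground truth; readers, writers and preprocessing for
    IBD/HBD segment tables, genetic maps and sample metadata; hierarchical
    Louvain community detection on IBD-sharing networks; non-negative
    least-squares ancestry profiling from band-limited IBD sharing;
    founder-effect summaries (within-cluster IBD, runs of homozygosity, FROH,
    consanguinity screening); allele-frequency drift statistics (Patterson's D
    with block jackknife, Hudson's FST); and grandparental-geography utilities
    including a simulated-p contingency test of denomination against cluster.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    igraph,
    mclust,
    pracma,
    vcfR,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
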