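Package: mirmodwalk
Title: miRNA-Gene Survival Modules by Pathway-Based Random Walk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Integrated survival analysis of sample-matched miRNA and mRNA
    expression on pathway graphs. Screens survival-associated miRNAs and
    genes by mean-split Kaplan-Meier log-rank testing, selects survival
    pathways by hypergeometric enrichment with Benjamini-Hochberg control,
    scores pathway nodes by a random walk with restart seeded at survival
    genes and miRNA targets, extracts top-ranked core genes per pathway,
    assembles the bipartite miRNA-gene core module, cuts it into sub-modules
    by hierarchical clustering, and evaluates expression signatures as risk
    predictors by K-means grouping and nearest-centroid classification. A
    synthetic-cohort generator with a planted, co-expressed miRNA-gene
    module makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    survival,
    utils
Suggests:
    igraph,
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
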