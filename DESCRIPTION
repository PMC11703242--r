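Package: markerclimb
Title: Marker Gene Selection by Stochastic Hill Climbing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Selects cell-type-specific marker genes from clustered single-cell
    RNA-seq count data by maximizing a three-term objective over binary gene
    selection vectors: a differential marker score rewarding cluster-specific
    expression, a cosine-similarity penalty discouraging redundant markers, and
    a sparsity penalty discouraging large sets. Optimization is stochastic hill
    climbing with an exponentially decaying exploration rate, in constrained
    (fixed set size) and unconstrained modes, with a brute-force oracle for
    small candidate pools. Includes one-vs-rest Wilcoxon rank-sum and Welch
    t-test differential expression with Benjamini-Hochberg correction,
    benchmark metrics (log-ratio difference, median cosine similarity) with
    median-based rank aggregation, and a negative-binomial simulator of
    clustered counts with planted markers for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
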