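Package: polyshock
Title: Transcriptome-Shock Analysis of Synthetic Allopolyploids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for dissecting transcriptome shock in a
    synthetic allotetraploid and its diploid progenitors from gene-level
    RNA-seq counts: TPM normalization and in-silico 1:1 parental mix
    construction, reciprocal-best-hit homoeolog pairing with NG86 Ka/Ks and
    promoter divergence, a self-contained negative-binomial Wald test for
    differential expression, homoeolog expression bias (HEB) calling and
    tracing, Flagel-Wendel net HEB, seven-category cis/trans classification
    of homoeolog-specific expression (HSE), weighted co-expression networks
    with topological overlap, homoeolog expression connectivity (HEC)
    scoring, quadruplet rewiring classification, and spike-development gene
    calls. A synthetic-data generator with known per-pair ground truth
    (cis/trans effects, bias trajectories, planted modules, planted
    differential expression) makes every stage testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
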