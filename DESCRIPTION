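Package: mcfuse
Title: Source-Free Multi-Source Transfer Learning via Multivariate Maximal Correlation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Combines the penultimate-layer features of several black-box
    pre-trained classifiers into a classifier for a new target task using only
    a few labelled target samples. Per-source correlation functions and group
    weights are learned by maximizing the aggregate Hirschfeld-Gebelein-Renyi
    maximal correlation between source features and the target label over a
    star-shaped dependence graph (network maximal correlation, fitted by
    alternating conditional expectation). Includes the discrete maximal
    correlation engine with its SVD oracle, a synthetic multi-source scenario
    generator with known ground-truth source informativeness, evaluation
    utilities (k-shot sweeps, source-weight stability, leave-one-source-out
    ablation), and rank-based method comparison (Friedman, Kruskal-Wallis,
    Nemenyi and Bonferroni-Dunn critical differences).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    grDevices,
    jsonlite,
    nnet,
    stats,
    tools,
    utils,
    yaml
Suggests:
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
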