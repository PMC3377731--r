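Package: mirnorm
Title: Benchmarking Normalization Strategies for One-Color miRNA Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for comparing normalization strategies on one-color miRNA
    expression data from hybridization arrays and RT-qPCR cards. Implements
    seven normalization methods (reference gene index, global geometric mean,
    quantile, rank-invariant selection, cyclic loess, loessM, and generalized
    Procrustes analysis of replicate groups), reference-gene stability scoring
    (geNorm, NormFinder), permutation-based SAM differential expression with
    relative-quantification (delta-delta-Cq) arithmetic, and the evaluation
    metrics used to compare them: inter-replicate standard deviations, ROC/AUC,
    Jaccard concordance of differential-expression lists within and across
    platforms, fold-change compression regressions and symmetry statistics.
    A seeded synthetic two-platform study generator with known ground truth
    makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    limma,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
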