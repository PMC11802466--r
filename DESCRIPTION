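Package: hmpattern
Title: Scale-Invariant Histone-Modification Patterns for Gene Expression
    Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Learns short, scale-invariant shape templates ("patterns") in
    binned histone-modification ChIP-seq signal around transcription start
    sites using standard particle swarm optimisation (SPSO2007), counts
    pattern occurrences per gene by sliding-window Pearson correlation, and
    uses the counts as features for a gradient-boosted tree classifier of
    binary (above/below median) gene-expression level.  Redundant patterns
    are pruned by backward elimination on a validation set and classifier
    hyperparameters are tuned with the same swarm optimiser.  Every
    prediction can be decomposed into per-feature log-odds contributions,
    aggregated into per-bin promoter importance maps, and transferred
    across samples.  A synthetic-data generator with planted motifs makes
    the whole pipeline testable without external ChIP-seq data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils,
    withr,
    xgboost
LinkingTo: Rcpp
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
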