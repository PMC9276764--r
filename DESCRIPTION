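Package: erparallel
Title: Simulation and Inference of Parallel Polygenic Adaptation in
    Evolve-and-Resequence Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward Wright-Fisher simulation of replicated
    Evolve-and-Resequence (E&R) experiments under multiplicative and
    epistatic fitness models, with a Pool-seq observation layer
    (pool subsampling plus read sampling), neutral-quantile detection of
    selected alleles, selection-coefficient estimation from allele
    frequency time series, drift-adjusted CMH/chi-square and
    linear-mixed-model tests, replicate-parallelism statistics
    (pairwise Jaccard index and replicate frequency spectrum), and
    sequential approximate Bayesian computation to estimate the strength
    of synergistic epistasis from parallelism summary statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    lme4,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo:
    Rcpp
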