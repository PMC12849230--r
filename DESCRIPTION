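Package: brainfp
Title: Brain Fingerprinting from Parcellated fMRI Time Series by Deep Metric Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Encodes parcellated resting-state BOLD time series into
    individual-specific embedding vectors ("brain fingerprints") with a
    windowed transformer trained under a triplet cosine-margin loss, and
    evaluates longitudinal individual identification (success rate,
    intra/inter distance ratio, silhouette coefficient, permutation nulls,
    connectome-correlation baseline). Includes attention-based token and
    region attribution with random-forest region weights, network
    contrasts, variogram-matching spatial surrogate tests for annotation
    and gene-expression maps, fingerprint-behaviour regression, kinship
    distance tests, and a seeded synthetic longitudinal cohort simulator
    with planted subject signatures for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    randomForest,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
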