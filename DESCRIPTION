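Package: cgrf
Title: Target-Gene Regulatory Network Inference from Time-Series Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hybrid workflow for inferring directed regulatory
    relationships around a single target gene from genes-by-timepoints
    expression data, designed for dense circadian time courses. Genes are
    grouped by fuzzy C-means clustering (with fuzzifier estimation and
    Gap-statistic guidance for the number of clusters), the target gene's
    trajectory is smoothed by tricube-weighted local polynomial regression
    with generalized cross-validation, every gene is ranked by its
    lock-step (Minkowski family) or dynamic-time-warping distance to the
    smoothed target, the number of relevant cluster genes is decided by an
    incremental Wilcoxon signed-rank agreement test with cross-cluster
    rescue of nearby genes, and a first-order vector autoregression over
    the selected genes yields signed directed edges weighted by lagged
    partial correlations, alongside undirected dynamic (functional)
    partial-correlation edges. Includes a synthetic-data generator with
    planted cluster structure and a planted regulatory core, an
    end-to-end pipeline runner, and ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
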