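Package: engraftr
Title: Ecological Outcomes and Predictive Modeling of Fecal Microbiota
    Transplant Engraftment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies every genus of a donor/pre-FMT/post-FMT sample triad
    into six ecological outcomes (colonization, rejection, coexistence,
    persistence, novel, loss) from presence/absence at the genus level,
    computes the alpha and beta diversity metrics used alongside
    (observed richness, Pielou evenness, Faith phylogenetic diversity,
    Jaccard, Bray-Curtis, unweighted and weighted UniFrac, PCoA, PERMANOVA),
    and predicts per-recipient colonization and rejection from 17 pre-FMT
    microbiome features with a repeated cross-validated elastic net fit by
    cyclic coordinate descent. A synthetic-cohort generator with known
    ground truth makes the whole pipeline testable without sequencing data,
    and a reproducible pipeline runner chains all stages from a YAML
    configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    glmnet,
    optparse,
    picante,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
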