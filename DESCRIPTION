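Package: hclink
Title: Link Prediction on Heterogeneous Attributed Networks via
    Hierarchies of Overlapping Multi-Type Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts new ncRNA-disease associations from an attributed
    heterogeneous network in three stages: (1) every ncRNA-disease pair is
    scored with a degree of certainty in [0,1] by comparing the attribute
    profiles of meta-path sequences (fuzzy max composition over meta-paths);
    (2) the scored pairs are organized into a hierarchy of overlapping
    multi-type clusters, starting from bicliques of pairs above a score
    threshold and greedily merged in order of cluster cohesiveness; (3) each
    hierarchy level acts as a link predictor by aggregating the cohesiveness
    of the clusters a pair falls in (maximum, minimum, average, or evidence
    combination). Includes a ranking-based evaluation protocol (k-fold
    positive-edge holdout, TPR@k and its area, ROC/PR under an
    unknowns-as-negatives assumption) and a synthetic-network generator with
    planted multi-type clusters for end-to-end testing.
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
    pracma,
    pROC,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
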