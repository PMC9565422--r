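Package: domainsalvage
Title: Unsupervised Adversarial Domain Adaptation for Multi-Site Image Classifiers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring and mitigating dataset shift when image
    classifiers trained at one site are deployed at another. Implements a
    conditional image-translation generator/discriminator trained with
    Wasserstein adversarial, gradient-penalty, domain-classification,
    cycle-consistency and semantic-consistency losses; the translate-then-
    fine-tune adaptation workflow; a synthetic multi-domain image benchmark
    with controlled, label-preserving domain shift; and deployment evaluation
    metrics (rank-based AUC with bootstrap confidence intervals, salvage,
    relative change, calibration curves, and domain spread across data
    fractions).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    png,
    jsonlite,
    yaml,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
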