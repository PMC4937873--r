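Package: leadsens
Title: Quantitative Genetics of Variation in Sensitivity to Lead Exposure in Inbred Line Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying and mapping genetic variation in
    sensitivity to a toxic exposure (lead) across a panel of fully inbred
    lines, in the style of Drosophila Genetic Reference Panel studies.
    Provides a synthetic-panel generator with genotype-by-environment
    structure; mixed-model ANOVA variance partitioning and broad-sense
    heritability; single-marker genome-wide association of sensitivity
    phenotypes with covariate adjustment, minor-allele-frequency filtering,
    quantile-quantile diagnostics and pairwise linkage disequilibrium;
    good/poor performer classification with logistic allele enrichment under
    Bonferroni correction; candidate-gene interaction-subnetwork extraction
    under a one-bridge rule with a largest-cluster randomization test; and
    mutant-validation ANOVA with a combined-SEM sensitivity statistic.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    lme4,
    lmerTest,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
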