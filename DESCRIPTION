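Package: rvburden
Title: Rare Coding Variant Burden Meta-Analysis for Gene Discovery
Version: 0.1.0
Authors@R: person("Artifact", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Case-control rare-coding-variant gene discovery: ultra-rare
    variant filters and consequence-class taxonomy (PTV, MPC-binned missense),
    stratified Cochran-Mantel-Haenszel burden tests with Mantel-Haenszel odds
    ratios and Robins-Breslow-Greenland confidence intervals, de novo mutation
    Poisson enrichment from trios, gated Fisher combined-probability
    meta-analysis with a minimum-P final statistic and explicit multiplicity
    accounting (Bonferroni and Benjamini-Hochberg), and gene-set burden
    enrichment by Firth penalized logistic regression. Includes a synthetic
    exome-study generator with planted odds ratios for calibration and power
    testing, and a command-line pipeline.
License: MIT
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0),
    VariantAnnotation
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
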