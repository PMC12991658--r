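Package: stabfm
Title: Stability-Guided Genetic Fine-Mapping with Permutation-Based
    Causal-SNP Posteriors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Non-parametric genetic fine-mapping via permutation-based
    causal-SNP posterior probabilities (PICS), with a stability-guided
    layer that re-runs the fine-mapper on ancestry-defined slices of the
    cohort and prioritises variants that are consistently supported
    across slices. Includes the companion cis-eQTL phenotype simulator
    with environmental-heterogeneity scenarios, recovery and
    method-agreement evaluation statistics, and annotation-enrichment
    comparison tests (Wilcoxon, trend tests, Benjamini-Hochberg
    correction) for downstream interpretation of fine-mapped variants.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    optparse
Config/testthat/edition: 3
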