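Package: idas
Title: Interpretable Classification of Differential-Abundance Gene Signatures
    by Nested ANOVA Model Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies genes downstream of a differential-abundance analysis
    into main-effect, interaction-effect, additive-effect and non-significant
    categories across two or three experimental factors, using staged
    comparisons of nested ANOVA models on log2 pseudobulk expression.
    Two-way designs are handled with fixed-effect F-tests; three-way designs
    add a per-subject random intercept and use maximum-likelihood ratio
    tests. Each category is then interpreted by post-hoc differential
    expression with empirical-Bayes moderated t-statistics, yielding
    cell-state markers, phenotype signatures and cell-state-specific
    phenotype markers. A spatial front end converts spatially resolved
    expression into per-sample nearest-neighbor correlation features that
    feed the same classifier, and a synthetic-data module generates
    pseudobulk, single-cell and spatial datasets with known per-gene ground
    truth for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    lme4,
    lmerTest,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    limma,
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
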