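Package: abbscore
Title: Allele Balance Bias Scoring and Genotype Callability Filtering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects genomic positions affected by systematic sequencing or
    alignment errors from the recurrent deviation of observed versus expected
    allele balance across a cohort of short-read samples. Models the expected
    allele balance per diploid genotype (binomial for heterozygotes,
    zero/one-inflated beta for homozygotes), aggregates per-sample deviations
    into per-position bias statistics, trains a logistic-regression
    callability classifier with a precision-mapped ABB score and confidence
    bins, filters and annotates VCF callsets, and re-evaluates rare-variant
    association candidates whose case/control burden is better explained by
    allele-balance bias than by true association. Includes a synthetic cohort
    simulator with known genotype and bias ground truth.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    fitdistrplus,
    mclust,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
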