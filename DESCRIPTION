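Package: krassig
Title: Cross-Tumour KRAS Gene-Signature Discovery and Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering and validating transcriptional signatures of
    oncogenic KRAS across experimental systems and patient cohorts. Implements
    empirical-Bayes moderated differential expression with the B log-odds
    statistic, a cross-system candidate intersection rule, preranked gene-set
    enrichment with permutation significance and leading-edge recurrence
    filtering, per-sample signature scoring (geometric-mean and z-summation)
    with logistic status classification and ROC evaluation, Kaplan-Meier,
    log-rank and Cox survival stratification, standardized-mean-difference
    meta-analysis, hypergeometric category enrichment, and Chou-Talalay
    median-effect combination-index analysis of two-drug synergy. A synthetic
    data module generates multi-cohort expression, survival and dose-response
    inputs with known ground truth so the whole pipeline is testable end to
    end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    metafor
Config/testthat/edition: 3
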