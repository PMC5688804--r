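Package: tnbctriage
Title: Multi-Omics Target Discovery for Triple-Negative Breast Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable re-implementation of a triple-negative breast cancer
    (TNBC) target-discovery pipeline. Classifies tumor receptor status (ER,
    PR, HER2) from expression with two-component Gaussian mixtures selected
    by immunohistochemistry concordance, calls differentially expressed
    genes with an empirical-Bayes moderated t-statistic and
    Benjamini-Hochberg FDR under fold-change gates, integrates promoter CpG
    island methylation (beta/M-value transforms, island/shore/shelf context,
    nearest-TSS mapping) and protein-level fold-change concordance, tests
    category enrichment with the Wallenius noncentral hypergeometric
    distribution, and ranks druggable candidate targets through a
    novelty/structure/ligandability triage cascade. Ships a synthetic-cohort
    generator with planted ground truth so the full pipeline is testable
    end-to-end without controlled-access data.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    limma,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
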