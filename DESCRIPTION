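Package: hlabench
Title: Consensus Benchmarking of HLA Genotyping and HLA-Driven Immune
    Survival Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a consensus ("benchmark") HLA genotype per sample and
    gene by allelic voting across the calls of multiple in-silico HLA
    genotyping tools, scores each tool against that benchmark (recall,
    accuracy, per-allele general error rates and pairwise specific error
    rates), and produces an integrated genotype from the top-ranked tools.
    Downstream, it computes per-sample immune cytolytic activity (CYT, the
    geometric mean of GZMA and PRF1 TPM), tumor mutation burden (TMB) from
    MAF-style somatic mutation tables, HLA supertype presence with optional
    loss-of-heterozygosity adjustment, and "Gun-Bullet" supertype-by-TMB
    stratification, and compares groups with Kaplan-Meier curves, log-rank
    tests and Cox proportional-hazards models. A seeded synthetic-cohort
    generator emulates multi-tool calls with tool-specific confusion pairs
    and dropout, expression coupled to an HLA-strength-by-TMB interaction,
    and proportional-hazards survival driven by CYT, so the whole pipeline
    is testable without controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
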