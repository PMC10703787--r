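Package: mksers
Title: MKS/ERS Metagene Stratification of ER+/HER2- Breast Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Stratifies ER+/HER2- breast tumours into four molecular
    subgroups by median-splitting two metagenes, a 12-gene mitosis kinase
    score (MKS) and a 4-gene estrogen-related score (ERS), computed from
    log-scale expression matrices with correlation-based filtering of
    discordant probes.  Provides the downstream analyses the stratification
    feeds: mRNA-based receptor calling, pathological-response and Ki67
    endpoint coding, tumour mutational burden and per-gene mutation
    frequencies from MAF-like tables with Cochran-Mantel-Haenszel tests,
    published-signature panel scoring, Kaplan-Meier / log-rank / univariate
    Cox survival comparison, and median-unbiased (mid-p) exact conditional
    odds-ratio estimation for response rates.  Includes a synthetic
    multi-cohort generator with known latent structure so every pipeline
    stage is testable without access to the original cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
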