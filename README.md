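# mksers

Stratification of ER+/HER2− breast cancer by two expression metagenes —
a 12-gene **mitosis kinase score (MKS)** and a 4-gene **estrogen-related
score (ERS)** — and the downstream analyses that stratification feeds.
The package targets translational analysts who have a log-scale
expression matrix, a clinical table and (optionally) a MAF-style
mutation table, and want reproducible subgroup calls plus the standard
outcome statistics.

Each metagene is the unweighted mean of its member genes on the log2
scale (MKS: PLK1, CDK1, BUB1B, NEK2, TTK, MELK, PLK4, CHEK1, AURKA,
AURKB, BUB1, PBK; ERS: BCL2, ESR1, PGR, SCUBE2), after resolving
signature members to matrix features (probe-set IDs on Affymetrix
platforms, symbols elsewhere) and discarding probes whose pairwise
correlation places them outside the dominant cluster at r < 0.4
(average linkage on 1 − r, cut at 0.6). Samples split at the
cohort-specific median of each score — high means strictly above — into
four subgroups (`MKShi_ERSlo`, `MKShi_ERShi`, `MKSlo_ERSlo`,
`MKSlo_ERShi`), or into two in ERS-only mode.

Downstream, the package provides:

- endpoint coding: pathological response (pathR = RCB 0/I vs RD =
  RCB II/III, pCR = RCB 0) and Ki67 endocrine response (< 10%);
  mRNA-based receptor calling (ESR1 log2 FPKM > 2.145, ERBB2 > 6.32)
  with IHC priority;
- the **median-unbiased exact conditional odds ratio** with mid-p
  confidence limits, built on a log-space implementation of Fisher's
  noncentral hypergeometric distribution: the estimate ψ̂ solves
  0.5·P(X = a; ψ) + P(X > a; ψ) = 0.5 conditional on both table margins;
- tumour mutational burden (coding mutations per exome, silent
  included), top-mutated-gene ranking with non-driver exclusion, and
  Cochran–Mantel–Haenszel frequency tests across subgroups;
- Kaplan–Meier / log-rank / univariate Cox comparisons (via the
  survival package), the pooled Student's t-test, and a logistic Wald
  interaction test for arm × stratum effects on a binary response;
- a synthetic multi-cohort generator (`simulate_cohort()`) with known
  latent structure, plus deterministic trial fixtures reconstructed from
  published counts, so the whole pipeline is testable without any
  external data.

## Worked example

```r
library(mksers)

cohort <- simulate_cohort(cohort_config(n_samples = 1000, seed = 101))
write_cohort(cohort, "results/cohort")

res <- run_pipeline(list(
  expression = "results/cohort/expression.tsv",
  platform   = "synthetic_log2",
  clinical   = "results/cohort/clinical.csv",
  mutations  = "results/cohort/mutations.maf.tsv",
  out_dir    = "results/pipeline"))

table(res$labels$subgroup)
#> MKShi_ERShi MKShi_ERSlo MKSlo_ERShi MKSlo_ERSlo
#>         204         296         296         204

res$comparisons$pcr_or_MKShi_ERSlo$estimate
#> [1] 2.975   # pCR odds ratio, experimental vs control arm
```

The pipeline writes `scores.tsv`, `labels.tsv`, `tmb.tsv`,
`gene_frequency_tests.tsv`, `comparisons.json` and a `provenance.json`
recording every threshold actually used. On this simulated cohort the
classified subgroups recover the generator's planted contrasts: 4-year
event-free survival 70% vs 92% between `MKShi_ERSlo` and `MKShi_ERShi`
(log-rank p = 6.2e-09), median burden 40 vs 28 coding mutations, and
TP53 mutated in 33.8% of `MKShi_ERSlo` vs 9–14% elsewhere (CMH
p = 2.1e-15) — numbers printed by `analysis/03_outcomes.R` and
`analysis/04_genomics.R`.

The deterministic trial fixture reproduces the published stratified
odds ratios exactly:

```r
fx <- make_ispy2_fixture()
midp_median_unbiased_or(fx$erslo["a"], fx$erslo["b"], fx$erslo["c"], fx$erslo["d"])
#> odds ratio 2.647 (95% CI 0.876-8.223) [midp_median_unbiased]
```

The `analysis/` directory holds the numbered drivers
(`01_simulate.R` … `05_trial_fixtures.R`) that run the full narrative —
simulate, classify, outcomes, genomics, trial fixtures — writing tables
under `results/`.

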