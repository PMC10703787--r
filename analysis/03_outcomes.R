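#!/usr/bin/env Rscript
# Clinical-outcome comparisons on the classified cohort: pCR odds ratios
# by arm within each subgroup, and event-free survival between the two
# highly proliferative subgroups.

suppressPackageStartupMessages(library(mksers))

labels <- read.delim("results/pipeline/labels.tsv")
clinical <- read.csv("results/cohort/clinical.csv")
clinical <- merge(labels[, c("sample_id", "subgroup")], clinical,
                  by = "sample_id")
resp <- classify_pathological_response(clinical$rcb_class)

cat("pCR rate by subgroup and arm:\n")
print(round(100 * tapply(resp$pcr,
                         list(clinical$subgroup, clinical$arm), mean), 1))

for (sg in c("MKShi_ERSlo", "MKShi_ERShi")) {
  sel <- clinical$subgroup == sg
  t2 <- table(factor(clinical$arm[sel],
                     levels = c("experimental", "control")),
              factor(resp$pcr[sel], levels = c(TRUE, FALSE)))
  or <- midp_median_unbiased_or(t2[1, 1], t2[1, 2], t2[2, 1], t2[2, 2])
  cat(sprintf("%s: pCR OR (experimental vs control) %.2f (95%% CI %.2f-%.2f)\n",
              sg, or$psi_hat, or$ci_low, or$ci_high))
}

sel <- clinical$subgroup %in% c("MKShi_ERShi", "MKShi_ERSlo")
km <- km_estimate(clinical$time_years[sel], clinical$event[sel],
                  clinical$subgroup[sel])
lr <- logrank_test(clinical$time_years[sel], clinical$event[sel],
                   clinical$subgroup[sel])
cx <- cox_univariate(clinical$time_years[sel], clinical$event[sel],
                     factor(clinical$subgroup[sel],
                            levels = c("MKShi_ERSlo", "MKShi_ERShi")))
cat(sprintf("4-year event-free survival: %.0f%% (MKShi_ERSlo) vs %.0f%% (MKShi_ERShi)\n",
            100 * km_survival_at(km, 4, "MKShi_ERSlo"),
            100 * km_survival_at(km, 4, "MKShi_ERShi")))
cat(sprintf("log-rank chi-square %.2f (df %d), p = %.2g\n",
            lr$statistic, lr$df, lr$p_value))
cat(sprintf("Cox HR (MKShi_ERShi vs MKShi_ERSlo) %.2f (95%% CI %.2f-%.2f), p = %.2g\n",
            cx$hr, cx$ci_low, cx$ci_high, cx$p_value))

out <- data.frame(
  measure = c("surv4_MKShi_ERSlo", "surv4_MKShi_ERShi",
              "logrank_p", "cox_hr"),
  value = c(km_survival_at(km, 4, "MKShi_ERSlo"),
            km_survival_at(km, 4, "MKShi_ERShi"), lr$p_value, cx$hr))
write.table(out, "results/outcomes.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Summary written to results/outcomes.tsv\n")
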