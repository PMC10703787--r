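#!/usr/bin/env Rscript
# The deterministic trial fixtures: stratified pCR odds ratios with the
# arm-by-stratum interaction test, and Ki67 endocrine-response coding.

suppressPackageStartupMessages(library(mksers))

fx <- make_ispy2_fixture()
for (stratum in c("erslo", "ershi")) {
  t2 <- fx[[stratum]]
  or <- midp_median_unbiased_or(t2["a"], t2["b"], t2["c"], t2["d"])
  cat(sprintf("%s: pCR %d/%d vs %d/%d, OR %.2f (95%% CI %.2f-%.2f)\n",
              toupper(stratum), t2["a"], t2["a"] + t2["b"], t2["c"],
              t2["c"] + t2["d"], or$psi_hat, or$ci_low, or$ci_high))
}
resp <- classify_pathological_response(fx$clinical$rcb_class)
it <- interaction_test(resp$pcr, fx$clinical$arm, fx$clinical$ers)
cat(sprintf("Arm x ERS interaction (Wald): p = %.3f\n", it$p_value))

pk <- make_poetic_fixture()
ki <- classify_ki67_response(pk$ki67_post_pct)
tab <- table(pk$subgroup, ki)
cat("Ki67 endocrine non-response by subgroup:\n")
for (sg in rownames(tab)) {
  n <- sum(tab[sg, ])
  cat(sprintf("  %s: %d of %d (%.1f%%) with Ki67 >= 10%%\n", sg,
              tab[sg, "non_responder"], n,
              100 * tab[sg, "non_responder"] / n))
}
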