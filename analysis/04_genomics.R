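#!/usr/bin/env Rscript
# Mutational landscape of the classified cohort: per-sample burden by
# subgroup, the top mutated driver genes, and CMH frequency tests.

suppressPackageStartupMessages(library(mksers))

labels <- read.delim("results/pipeline/labels.tsv")
muts <- read_maf("results/cohort/mutations.maf.tsv")
lab <- setNames(labels$subgroup, labels$sample_id)

tmb <- compute_tmb(muts, names(lab))
cat("Median TMB (coding mutations) by subgroup:\n")
print(tapply(tmb, lab, median))
tt <- students_t_test(tmb[lab == "MKShi_ERSlo"],
                      tmb[lab == "MKShi_ERShi"])
cat(sprintf("MKShi_ERSlo vs MKShi_ERShi burden: t = %.2f, p = %.2g\n",
            tt$t, tt$p_value))

top <- top_mutated_genes(muts, names(lab), k = 15)
cat("Top mutated genes (after non-driver exclusion):\n")
print(head(top, 5))

named <- intersect(rownames(default_mut_freq()), top$gene)
res <- frequency_table_and_test(muts, lab, named)
cat("Mutation frequency by subgroup with CMH general-association tests:\n")
print(round(res$frequencies, 3))
print(res$tests[, c("gene", "statistic", "df", "p_value")])

out <- cbind(res$tests, as.data.frame(res$frequencies))
write.table(out, "results/mutation_tests.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Written to results/mutation_tests.tsv\n")
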