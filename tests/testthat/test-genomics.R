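test_that("TMB counts coding classes only, silent included, intron excluded", {
  muts <- mut_df(rep("s1", 6), paste0("g", 1:6),
                 c(rep("Missense_Mutation", 3), rep("Silent", 2),
                   "Intron"))
  expect_identical(compute_tmb(muts, "s1"), c(s1 = 5L))
  expect_identical(compute_tmb(muts, c("s1", "s2")),
                   c(s1 = 5L, s2 = 0L))
})

test_that("TMB is additive and permutation-invariant over records", {
  set.seed(30)
  muts <- mut_df(sample(paste0("s", 1:4), 40, replace = TRUE),
                 sample(paste0("g", 1:10), 40, replace = TRUE),
                 sample(c(CODING_CLASSES, "Intron"), 40, replace = TRUE))
  samples <- paste0("s", 1:4)
  t1 <- compute_tmb(muts, samples)
  expect_identical(compute_tmb(muts[sample(nrow(muts)), ], samples), t1)
  expect_identical(compute_tmb(rbind(muts, muts), samples), 2L * t1)
})

test_that("unknown variant classifications warn and are excluded, or error on request", {
  muts <- mut_df(c("s1", "s1"), c("g1", "g2"),
                 c("Missense_Mutation", "MadeUpClass"))
  expect_warning(t1 <- compute_tmb(muts, "s1"), "unknown variant")
  expect_identical(t1, c(s1 = 1L))
  expect_error(compute_tmb(muts, "s1", on_unknown = "error"),
               "unknown variant")
})

test_that("gene ranking respects exclusion lists, alphabetical ties, and k", {
  muts <- mut_df(c(paste0("s", 1:5), paste0("s", 1:3), paste0("s", 1:3)),
                 c(rep("geneA", 5), rep("geneB", 3), rep("geneC", 3)))
  top <- top_mutated_genes(muts, paste0("s", 1:10),
                           exclusion = "geneB")
  expect_identical(top$gene, c("geneA", "geneC"))
  expect_equal(top$frequency, c(0.5, 0.3))
  expect_identical(top_mutated_genes(muts, paste0("s", 1:10), k = 100,
                                     exclusion = character(0))$gene,
                   c("geneA", "geneB", "geneC"))  # tie B/C -> alphabetical
})

test_that("planted mutation frequencies are recovered in ranked order", {
  set.seed(31)
  n <- 400
  samples <- sprintf("s%03d", 1:n)
  planted <- c(high = 0.5, mid = 0.3, low = 0.1)
  recs <- lapply(names(planted), function(g)
    mut_df(samples[runif(n) < planted[g]], g))
  muts <- do.call(rbind, recs)
  top <- top_mutated_genes(muts, samples)
  expect_identical(top$gene, c("high", "mid", "low"))
  expect_equal(top$frequency, unname(planted), tolerance = 0.2)
})

test_that("equal mutation proportions give a zero CMH statistic", {
  samples <- sprintf("s%03d", 1:80)
  labels <- setNames(rep(c("A", "B", "C", "D"), each = 20), samples)
  mutated <- samples[seq(1, 80, by = 4)]  # 5 per group
  res <- frequency_table_and_test(mut_df(mutated, "TP53"), labels, "TP53")
  expect_equal(unname(res$frequencies["TP53", ]), rep(0.25, 4))
  expect_equal(res$tests$statistic, 0, tolerance = 1e-12)
  expect_equal(res$tests$p_value, 1)
})

test_that("the single-stratum 2x2 statistic matches the Mantel-Haenszel closed form", {
  # direct formula oracle: (n-1) (ad - bc)^2 / (r1 r2 c1 c2)
  for (cells in list(c(5, 15, 10, 10), c(3, 7, 12, 18), c(8, 2, 4, 16))) {
    a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
    n <- a + b + c + d
    oracle <- (n - 1) * (a * d - b * c)^2 /
      ((a + b) * (c + d) * (a + c) * (b + d))
    samples <- sprintf("s%03d", 1:n)
    labels <- setNames(rep(c("G1", "G2"), c(a + b, c + d)), samples)
    mutated <- c(samples[seq_len(a)], samples[a + b + seq_len(c)])
    res <- frequency_table_and_test(mut_df(mutated, "g"), labels, "g")
    expect_equal(res$tests$statistic, oracle, tolerance = 1e-10)
    expect_gte(res$tests$statistic, 0)
  }
})

test_that("frequencies equal brute-force counting and absent genes are skipped with a note", {
  samples <- paste0("s", 1:10)
  labels <- setNames(rep(c("A", "B"), each = 5), samples)
  muts <- mut_df(c("s1", "s2", "s6", "s1"), c("g1", "g1", "g1", "g1"))
  res <- frequency_table_and_test(muts, labels, c("g1", "g2"))
  expect_equal(res$frequencies["g1", ], c(A = 0.4, B = 0.2))
  expect_equal(res$frequencies["g2", ], c(A = 0, B = 0))
  expect_true(all(res$frequencies >= 0 & res$frequencies <= 1))
  expect_match(res$tests$note[2], "skipped")
  expect_true(is.na(res$tests$p_value[2]))
})

test_that("planted four-group TP53 frequencies are detected with high power", {
  set.seed(32)
  planted <- c(0.06, 0.12, 0.16, 0.34)
  n_group <- 500
  n_sims <- 200
  samples <- sprintf("s%04d", 1:(4 * n_group))
  labels <- setNames(rep(paste0("G", 1:4), each = n_group), samples)
  hits <- replicate(n_sims, {
    mutated <- samples[runif(4 * n_group) <
                         rep(planted, each = n_group)]
    res <- frequency_table_and_test(mut_df(mutated, "TP53"), labels,
                                    "TP53")
    res$tests$p_value < 1e-6
  })
  expect_gt(mean(hits), 0.95)
})

test_that("the stratified CMH route agrees with mantelhaen.test", {
  set.seed(33)
  n <- 200
  samples <- sprintf("s%03d", 1:n)
  labels <- setNames(sample(c("A", "B"), n, replace = TRUE), samples)
  stratum <- sample(c("x", "y"), n, replace = TRUE)
  mutated <- samples[runif(n) < ifelse(labels == "A", 0.4, 0.2)]
  res <- frequency_table_and_test(mut_df(mutated, "g"), labels, "g",
                                  stratum = stratum)
  arr <- table(factor(ifelse(samples %in% mutated, "mutated", "wildtype"),
                      levels = c("mutated", "wildtype")),
               factor(labels), factor(stratum))
  ref <- mantelhaen.test(arr, correct = FALSE)
  expect_equal(res$tests$statistic, unname(ref$statistic))
  expect_equal(res$tests$p_value, ref$p.value)
})

test_that("MAF column dialects are accepted", {
  tmp <- tempfile(fileext = ".tsv")
  writeLines(c("Tumor_Sample_Barcode\tHugo_Symbol\tVariant_Classification",
               "s1\tTP53\tMissense_Mutation"), tmp)
  df <- read_maf(tmp)
  expect_identical(df$sample_id, "s1")
  expect_identical(df$gene, "TP53")
  writeLines(c("sample_id\tgene\tvariant_classification",
               "s2\tPIK3CA\tSilent"), tmp)
  expect_identical(read_maf(tmp)$gene, "PIK3CA")
})
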