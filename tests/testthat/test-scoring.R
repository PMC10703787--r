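test_that("signature members resolve by probe ID on Affymetrix platforms", {
  set.seed(1)
  ids <- c(MKS_TABLE$probe_id, sprintf("2%05d_at", 1:20))
  mat <- latent_matrix(ids, rnorm(10), noise_sd = 1,
                       platform = "affy_hgu133a")
  feats <- resolve_features(mks_signature(), mat)
  expect_identical(feats, MKS_TABLE$probe_id)
  expect_identical(feats[1], "202240_at")  # PLK1
})

test_that("signature members resolve by symbol elsewhere, case-insensitively", {
  set.seed(2)
  ids <- c("bcl2", "ESR1", "Pgr", "SCUBE2", sprintf("DECOY%03d", 1:100))
  mat <- latent_matrix(ids, rnorm(8), noise_sd = 1, platform = "rnaseq_log2")
  expect_identical(resolve_features(ers_signature(), mat),
                   c("bcl2", "ESR1", "Pgr", "SCUBE2"))
})

test_that("an unrepresented signature signals an error", {
  mat <- latent_matrix(c("A", "B"), rnorm(5), noise_sd = 1)
  expect_error(resolve_features(ers_signature(), mat),
               "signature unrepresented")
})

test_that("concordant probes are all retained by the correlation filter", {
  set.seed(3)
  mat <- latent_matrix(paste0("p", 1:5), rnorm(60), noise_sd = 0.2)
  r <- cor(t(mat$values))
  expect_true(all(r[upper.tri(r)] > 0.8))
  expect_identical(filter_discordant_probes(mat, paste0("p", 1:5)),
                   paste0("p", 1:5))
})

test_that("an anti-correlated probe is excluded, concordant ones kept", {
  set.seed(4)
  lat <- rnorm(80)
  mat <- latent_matrix(paste0("p", 1:5), lat, noise_sd = 0.4)
  mat$values[5, ] <- 14 - mat$values[5, ]  # sign-flip a noisy copy
  r <- cor(t(mat$values))
  expect_true(all(r[5, 1:4] < -0.5))           # construction check
  expect_true(all(r[1:4, 1:4][upper.tri(diag(4))] > 0.6))
  kept <- filter_discordant_probes(mat, paste0("p", 1:5))
  expect_identical(kept, paste0("p", 1:4))
})

test_that("a pair just under the correlation threshold splits; the tie-break keeps the lexicographically smaller singleton", {
  set.seed(5)
  mat <- exact_corr_pair(0.39, ids = c("pB", "pA"))
  expect_equal(cor(mat$values["pB", ], mat$values["pA", ]), 0.39,
               tolerance = 1e-12)
  expect_identical(filter_discordant_probes(mat, c("pB", "pA"),
                                            r_min = 0.4), "pA")
  # and just above the threshold the pair stays together
  mat2 <- exact_corr_pair(0.41, ids = c("pB", "pA"))
  expect_setequal(filter_discordant_probes(mat2, c("pB", "pA"),
                                           r_min = 0.4), c("pA", "pB"))
})

test_that("zero-variance features are excluded with a degenerate-variance warning", {
  set.seed(6)
  mat <- latent_matrix(paste0("p", 1:3), rnorm(30), noise_sd = 0.2)
  mat$values[3, ] <- 5
  expect_warning(kept <- filter_discordant_probes(mat, paste0("p", 1:3)),
                 "degenerate variance")
  expect_identical(kept, c("p1", "p2"))
})

test_that("the probe filter is idempotent", {
  set.seed(7)
  for (i in 1:5) {
    lat <- rnorm(50)
    mat <- latent_matrix(paste0("p", 1:8), lat, noise_sd = runif(1, 0.3, 2))
    kept <- filter_discordant_probes(mat, paste0("p", 1:8))
    if (length(kept) >= 2)
      expect_identical(filter_discordant_probes(mat, kept), kept)
  }
})

test_that("metagene scores equal an independent per-sample mean", {
  set.seed(8)
  mat <- latent_matrix(paste0("g", 1:12), rnorm(20), noise_sd = 2)
  sig <- gene_signature("test", paste0("g", 1:12))
  sc <- score_metagene(mat, sig, paste0("g", 1:12))
  brute <- apply(mat$values, 2, mean)
  expect_equal(unname(sc), unname(brute), tolerance = 1e-12)
})

test_that("single-gene signatures return the gene's row; constant matrices score the constant", {
  set.seed(9)
  mat <- latent_matrix(c("CCNE1", "other"), rnorm(10), noise_sd = 1)
  sig <- gene_signature("CCNE1", "CCNE1", aggregation = "single_gene")
  expect_equal(score_metagene(mat, sig, "CCNE1"),
               mat$values["CCNE1", ])
  cmat <- expr_matrix(matrix(3.25, 4, 6,
                             dimnames = list(paste0("g", 1:4),
                                             paste0("s", 1:6))))
  expect_equal(unname(score_metagene(cmat,
                                     gene_signature("c", paste0("g", 1:4)),
                                     paste0("g", 1:4))),
               rep(3.25, 6))
})

test_that("missing entries fall back to the within-sample available-feature mean", {
  m <- matrix(c(1, 3, NA, 5, 2, 4), 3, 2,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  mat <- expr_matrix(m)
  sig <- gene_signature("s", c("a", "b", "c"))
  sc <- score_metagene(mat, sig, c("a", "b", "c"))
  expect_equal(unname(sc), c(mean(c(1, 3)), mean(c(5, 2, 4))))
  mat$values[, 1] <- NA
  expect_error(score_metagene(mat, sig, c("a", "b", "c")),
               "all signature features missing")
})

test_that("imputation fills missing cells with the global observed minimum", {
  m <- matrix(c(2, 4, NA, 6), 2, 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  out <- impute_missing(expr_matrix(m))
  expect_equal(unname(out$values), matrix(c(2, 4, 2, 6), 2, 2))
  m2 <- matrix(c(1.5, 7, NA, NA, 3, NA), 2, 3,
               dimnames = list(c("a", "b"), c("s1", "s2", "s3")))
  out2 <- impute_missing(expr_matrix(m2))
  expect_equal(sum(out2$values == 1.5), 4)  # 1 observed + 3 imputed
  full <- latent_matrix(c("a", "b"), rnorm(4), noise_sd = 1)
  expect_identical(impute_missing(full)$values, full$values)
  allna <- expr_matrix(matrix(NA_real_, 2, 2,
                              dimnames = list(c("a", "b"), c("x", "y"))))
  expect_error(impute_missing(allna), "all-missing")
})

test_that("panel scoring records feature counts and tolerates unrepresented signatures", {
  set.seed(10)
  panel <- default_panel()
  expect_length(panel$IRPS$symbols, 35)
  lat <- rnorm(40)
  mat <- latent_matrix(panel$IRPS$symbols, lat, noise_sd = 0.3)
  expect_warning(st <- score_panel(mat, panel), "unrepresented")
  expect_lte(st$n_features_used[["IRPS"]], 35)
  expect_true(all(c("RBsig", "TILs") %in% st$unrepresented))
  # zero-noise: panel score is a copy of the latent
  expect_gt(cor(st$scores$IRPS, lat), 0.99)
})

test_that("panel scoring of a single-gene signature on a 1-gene matrix returns that row", {
  mat <- latent_matrix("CCNE1", rnorm(12), noise_sd = 1)
  st <- score_panel(mat, gene_signature("CCNE1", "CCNE1",
                                        aggregation = "single_gene"))
  expect_equal(st$scores$CCNE1, mat$values["CCNE1", ])
  expect_identical(st$n_features_used[["CCNE1"]], 1L)
})

test_that("scoring is invariant to sample and feature permutations", {
  set.seed(11)
  mat <- latent_matrix(paste0("g", 1:6), rnorm(15), noise_sd = 1)
  sig <- gene_signature("s", paste0("g", 1:6))
  sc <- score_metagene(mat, sig, paste0("g", 1:6))
  perm_s <- sample(colnames(mat$values))
  perm_f <- sample(rownames(mat$values))
  mat2 <- expr_matrix(mat$values[perm_f, perm_s])
  sc2 <- score_metagene(mat2, sig, perm_f)
  expect_equal(sc2[names(sc)], sc)
})

test_that("adding a constant shifts unweighted scores by that constant; unit weights equal the plain mean", {
  set.seed(12)
  mat <- latent_matrix(paste0("g", 1:5), rnorm(10), noise_sd = 1)
  sig <- gene_signature("s", paste0("g", 1:5))
  sigw <- gene_signature("s", paste0("g", 1:5),
                         weights = rep(1, 5), aggregation = "weighted_mean")
  sc <- score_metagene(mat, sig, paste0("g", 1:5))
  mat2 <- mat; mat2$values <- mat2$values + 1.7
  expect_equal(score_metagene(mat2, sig, paste0("g", 1:5)), sc + 1.7)
  expect_identical(score_metagene(mat, sigw, paste0("g", 1:5)), sc)
})

test_that("GMT files round-trip signatures including probes and weights", {
  path <- system.file("extdata", "mks_ers.gmt", package = "mksers")
  sigs <- read_gmt(path)
  expect_identical(sigs$MKS$symbols, MKS_TABLE$symbol)
  expect_identical(sigs$MKS$probe_ids, MKS_TABLE$probe_id)
  expect_identical(sigs$ERS$symbols, ERS_TABLE$symbol)
  w <- gene_signature("W", c("A", "B"), probe_ids = c("1_at", NA),
                      weights = c(2, 0.5), aggregation = "weighted_mean")
  tmp <- tempfile(fileext = ".gmt")
  write_gmt(list(w), tmp)
  back <- read_gmt(tmp)$W
  expect_identical(back$symbols, w$symbols)
  expect_identical(back$probe_ids, w$probe_ids)
  expect_identical(back$weights, w$weights)
  expect_identical(back$aggregation, "weighted_mean")
})

test_that("expression TSV round-trips including missing cells and linear-scale transform", {
  set.seed(13)
  mat <- latent_matrix(paste0("g", 1:4), rnorm(6), noise_sd = 1)
  mat$values[2, 3] <- NA
  tmp <- tempfile(fileext = ".tsv")
  write_expression_tsv(mat, tmp)
  back <- read_expression_tsv(tmp)
  expect_equal(back$values, mat$values, tolerance = 1e-9)
  lin <- expr_matrix(matrix(c(0, 1, 3, 7), 2, 2,
                            dimnames = list(c("a", "b"), c("x", "y"))),
                     platform = "rnaseq_linear")
  expect_equal(unname(lin$values), log2(matrix(c(0, 1, 3, 7), 2, 2) + 1))
  expect_identical(lin$platform, "rnaseq_log2")
})
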