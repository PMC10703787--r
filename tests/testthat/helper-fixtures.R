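# Small in-code fixtures shared across test files.

# features x samples matrix driven by a single latent vector plus noise;
# returns an expr_matrix with the given feature ids
latent_matrix <- function(feature_ids, latent, noise_sd = 0,
                          loading = 1, base = 7, platform = "generic") {
  k <- length(feature_ids)
  n <- length(latent)
  m <- base + outer(rep(loading, k), latent) +
    matrix(rnorm(k * n, 0, noise_sd), k, n)
  rownames(m) <- feature_ids
  colnames(m) <- sprintf("S%03d", seq_len(n))
  expr_matrix(m, platform = platform)
}

# two feature rows with an exact empirical Pearson correlation r
exact_corr_pair <- function(r, n = 50, ids = c("pA", "pB")) {
  x <- rnorm(n)
  z <- rnorm(n)
  z <- residuals(lm(z ~ x))
  x <- as.numeric(scale(x)); z <- as.numeric(scale(z))
  y <- r * x + sqrt(1 - r^2) * z
  m <- rbind(x, y) + 7
  rownames(m) <- ids
  colnames(m) <- sprintf("S%03d", seq_len(n))
  expr_matrix(m)
}

# minimal mutation data.frame
mut_df <- function(sample_id, gene, vc = "Missense_Mutation") {
  data.frame(sample_id = sample_id, gene = gene,
             variant_classification = rep_len(vc, length(sample_id)),
             stringsAsFactors = FALSE)
}

# independent enumeration oracle for the noncentral hypergeometric CDF,
# written with plain choose() arithmetic (no shared code with fnch_*)
fnch_cdf_oracle <- function(x, m1, m2, k, psi) {
  lo <- max(0, k - m2); hi <- min(m1, k)
  s <- lo:hi
  w <- choose(m1, s) * choose(m2, k - s) * psi^s
  sum(w[s <= x]) / sum(w)
}

# dense-grid oracle for the mid-p median-unbiased root: evaluates the
# mid-p tail on a fine log-spaced psi grid and interpolates the crossing
midp_root_grid_oracle <- function(a, b, c, d, n_grid = 4000) {
  m1 <- a + b; m2 <- c + d; k <- a + c
  lo <- max(0, k - m2); hi <- min(m1, k)
  s <- lo:hi
  grid <- exp(seq(log(1e-4), log(1e4), length.out = n_grid))
  q <- vapply(grid, function(psi) {
    w <- exp(lchoose(m1, s) + lchoose(m2, k - s) + s * log(psi))
    p <- w / sum(w)
    i <- a - lo + 1
    0.5 * p[i] + if (i < length(s)) sum(p[(i + 1):length(s)]) else 0
  }, numeric(1))
  if (all(q < 0.5) || all(q > 0.5)) return(NA_real_)
  i <- which(q >= 0.5)[1]
  # linear interpolation on the log scale between bracketing grid points
  l1 <- log(grid[i - 1]); l2 <- log(grid[i])
  exp(l1 + (0.5 - q[i - 1]) / (q[i] - q[i - 1]) * (l2 - l1))
}
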