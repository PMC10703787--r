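#' Synthetic cohort configuration
#'
#' Bundles every parameter of the synthetic multi-omic cohort generator.
#' Two latent axes drive the data: `m` (proliferation) and `e`
#' (ER signalling), drawn standard bivariate normal with correlation
#' `latent_corr`.  Signature member genes load on their latent; outcome
#' models are indexed by the true subgroup, the sign pattern of `(m, e)`.
#' Default outcome parameters are set to the response rates, hazards,
#' mutation frequencies and burden levels reported for ER+/HER2- cohorts
#' stratified this way (pCR 20.9/41.7 percent in the ERS-low stratum under
#' chemotherapy without/with immunotherapy, 9.8/12.5 in ERS-high; 4-year
#' distant-event-free survival 70 vs 94 percent in MKShi_ERSlo vs
#' MKShi_ERShi; TP53 mutated in 34/16/12/6 percent of
#' MKShi_ERSlo/MKShi_ERShi/MKSlo_ERSlo/MKSlo_ERShi; PIK3CA enriched at 52
#' percent in MKSlo_ERShi; median burden 43 vs 27 coding mutations).
#'
#' @param n_samples cohort size.
#' @param n_noise_genes independent decoy genes added to the matrix.
#' @param latent_corr correlation between the two latent axes.
#' @param loading_mean,loading_sd per-gene loading distribution on the
#'   driving latent.
#' @param noise_sd residual expression noise, log2 units.
#' @param base_expr mean log2 expression level.
#' @param treat_frac fraction randomised to the experimental arm.
#' @param pcr_prob 4 x 2 matrix of pCR probabilities, rows the subgroups,
#'   columns `control` / `experimental`.
#' @param rcb1_given_no_pcr probability that a non-pCR sample is RCB I.
#' @param hazard named vector of event hazards per subgroup (events/year).
#' @param censor_rate exponential censoring hazard (per year).
#' @param horizon administrative censoring time, years.
#' @param mut_freq genes x subgroups matrix of mutation probabilities.
#' @param tmb_mean named vector of negative-binomial TMB means per
#'   subgroup; `tmb_size` the NB size (dispersion) parameter.
#' @param ki67 list `(intercept, slope_m, suppression_ershi, sd)` for the
#'   post-endocrine-therapy Ki67 model (logit scale of Ki67/100).
#' @param seed integer seed; the same seed reproduces the cohort exactly.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_samples = 500L, n_noise_genes = 200L,
                          latent_corr = -0.3, loading_mean = 1,
                          loading_sd = 0.2, noise_sd = 0.5, base_expr = 7,
                          treat_frac = 0.5,
                          pcr_prob = default_pcr_prob(),
                          rcb1_given_no_pcr = 0.05,
                          hazard = default_hazard(),
                          censor_rate = 0.05, horizon = 5,
                          mut_freq = default_mut_freq(),
                          tmb_mean = default_tmb_mean(), tmb_size = 10,
                          ki67 = list(intercept = -3.16, slope_m = 1.2,
                                      suppression_ershi = 0.57, sd = 0.4),
                          seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples),
              n_noise_genes = as.integer(n_noise_genes),
              latent_corr = latent_corr, loading_mean = loading_mean,
              loading_sd = loading_sd, noise_sd = noise_sd,
              base_expr = base_expr, treat_frac = treat_frac,
              pcr_prob = pcr_prob,
              rcb1_given_no_pcr = rcb1_given_no_pcr, hazard = hazard,
              censor_rate = censor_rate, horizon = horizon,
              mut_freq = mut_freq, tmb_mean = tmb_mean,
              tmb_size = tmb_size, ki67 = ki67, seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

#' @rdname cohort_config
#' @export
default_pcr_prob <- function() {
  m <- rbind(MKSlo_ERShi = c(0.08, 0.08),
             MKSlo_ERSlo = c(0.08, 0.08),
             MKShi_ERShi = c(0.098, 0.125),
             MKShi_ERSlo = c(0.209, 0.417))
  colnames(m) <- c("control", "experimental")
  m
}

#' @rdname cohort_config
#' @export
default_hazard <- function() {
  # -log(S4)/4 for 4-year survival 94/94/94/70 percent
  c(MKSlo_ERShi = 0.0155, MKSlo_ERSlo = 0.0200, MKShi_ERShi = 0.0155,
    MKShi_ERSlo = 0.0892)
}

#' @rdname cohort_config
#' @export
default_mut_freq <- function() {
  m <- rbind(TP53    = c(0.06, 0.12, 0.16, 0.34),
             PIK3CA  = c(0.52, 0.33, 0.32, 0.33),
             CDH1    = c(0.25, 0.12, 0.08, 0.05),
             MAP3K1  = c(0.20, 0.10, 0.08, 0.04))
  colnames(m) <- SUBGROUP_LEVELS
  m
}

#' @rdname cohort_config
#' @export
default_tmb_mean <- function() {
  # means set so the negative-binomial median (size 10) hits the target
  # median burden of 24/27/27/43 coding mutations
  c(MKSlo_ERShi = 25.2, MKSlo_ERSlo = 28.2, MKShi_ERShi = 28.2,
    MKShi_ERSlo = 44.7)
}

validate_cohort_config <- function(cfg) {
  stopifnot(cfg$n_samples >= 4L, cfg$n_noise_genes >= 0L,
            abs(cfg$latent_corr) < 1, cfg$noise_sd >= 0,
            cfg$treat_frac >= 0, cfg$treat_frac <= 1,
            cfg$censor_rate > 0, cfg$horizon > 0, cfg$tmb_size > 0)
  if (!identical(rownames(cfg$pcr_prob), SUBGROUP_LEVELS) ||
      !identical(colnames(cfg$pcr_prob), c("control", "experimental")))
    stop("pcr_prob must be a 4 x 2 matrix with subgroup rows and ",
         "control/experimental columns")
  if (any(cfg$pcr_prob < 0 | cfg$pcr_prob > 1))
    stop("pcr_prob outside [0, 1]")
  if (!setequal(names(cfg$hazard), SUBGROUP_LEVELS) ||
      any(cfg$hazard <= 0))
    stop("hazard must be positive and keyed by the four subgroups")
  if (!identical(colnames(cfg$mut_freq), SUBGROUP_LEVELS))
    stop("mut_freq columns must be the four subgroups")
  if (any(cfg$mut_freq < 0 | cfg$mut_freq > 1))
    stop("mut_freq outside [0, 1]")
  if (!setequal(names(cfg$tmb_mean), SUBGROUP_LEVELS))
    stop("tmb_mean must be keyed by the four subgroups")
  invisible(cfg)
}

# how signature genes are wired to the latent axes: sign of the loading
# and a scale relative to loading_mean
panel_wiring <- function() {
  list(MKS = list(latent = "m", scale = 1),
       ERS = list(latent = "e", scale = 1),
       RBsig = list(latent = "m", scale = 0.8),
       IRPS = list(latent = "m", scale = 0.6),
       CCNE1 = list(latent = "m", scale = 0.8),
       TILs = list(latent = "e", scale = -0.7),
       GEP = list(latent = "e", scale = -0.7))
}

#' Simulate a synthetic multi-omic cohort
#'
#' Generates an expression matrix, clinical table, somatic mutation table
#' and ground-truth latent table with the joint structure the analysis
#' pipeline assumes: signature genes loading on two correlated latent axes
#' (immune-panel genes loading negatively on the ER axis, reproducing the
#' inverse TILs-ERS relationship), subgroup-dependent response
#' probabilities, exponential survival and censoring, per-gene mutation
#' frequencies, and negative-binomial mutation burden.  The truth table is
#' for validation only and is never consumed by the pipeline under test.
#'
#' @param cfg a [cohort_config()].
#' @return List of class `synthetic_cohort` with elements `expression`
#'   (an `expr_matrix`), `clinical` (data.frame), `mutations` (data.frame),
#'   `truth` (data.frame), `config`.
#' @export
simulate_cohort <- function(cfg = cohort_config()) {
  validate_cohort_config(cfg)
  set.seed(cfg$seed)
  n <- cfg$n_samples
  ids <- sprintf("S%04d", seq_len(n))

  # latent axes
  m <- stats::rnorm(n)
  e <- cfg$latent_corr * m +
    sqrt(1 - cfg$latent_corr^2) * stats::rnorm(n)
  # true subgroup: sign pattern of the latents about their cohort medians,
  # so a noiseless median split of the scores recovers it exactly
  subgroup <- factor(paste0(ifelse(m > stats::median(m), "MKShi", "MKSlo"),
                            "_",
                            ifelse(e > stats::median(e), "ERShi", "ERSlo")),
                     levels = SUBGROUP_LEVELS)

  # expression: signature genes load on their latent, decoys are noise
  wiring <- panel_wiring()
  sigs <- c(list(MKS = mks_signature(), ERS = ers_signature()),
            default_panel())
  blocks <- list()
  for (nm in names(wiring)) {
    sig <- sigs[[nm]]
    if (is.null(sig)) next
    lat <- if (wiring[[nm]]$latent == "m") m else e
    k <- length(sig$symbols)
    loadings <- wiring[[nm]]$scale *
      stats::rnorm(k, cfg$loading_mean, cfg$loading_sd)
    block <- cfg$base_expr + outer(loadings, lat) +
      matrix(stats::rnorm(k * n, 0, cfg$noise_sd), k, n)
    rownames(block) <- sig$symbols
    blocks[[nm]] <- block
  }
  expr <- do.call(rbind, blocks)
  expr <- expr[!duplicated(rownames(expr)), , drop = FALSE]
  if (cfg$n_noise_genes > 0L) {
    noise <- matrix(stats::rnorm(cfg$n_noise_genes * n, cfg$base_expr, 1),
                    cfg$n_noise_genes, n)
    rownames(noise) <- sprintf("NOISE%04d", seq_len(cfg$n_noise_genes))
    expr <- rbind(expr, noise)
  }
  colnames(expr) <- ids
  emat <- expr_matrix(expr, platform = "synthetic_log2")

  # clinical outcomes
  arm <- ifelse(stats::runif(n) < cfg$treat_frac, "experimental",
                "control")
  p_pcr <- cfg$pcr_prob[cbind(as.character(subgroup), arm)]
  pcr <- stats::runif(n) < p_pcr
  rcb <- ifelse(pcr, "0",
                ifelse(stats::runif(n) < cfg$rcb1_given_no_pcr, "I",
                       ifelse(stats::runif(n) < 0.55, "II", "III")))
  t_event <- stats::rexp(n, cfg$hazard[as.character(subgroup)])
  t_cens <- pmin(stats::rexp(n, cfg$censor_rate), cfg$horizon)
  time <- pmin(t_event, t_cens)
  event <- t_event <= t_cens
  ers_hi_true <- e > stats::median(e)
  eta <- cfg$ki67$intercept + cfg$ki67$slope_m * m -
    cfg$ki67$suppression_ershi * ers_hi_true +
    stats::rnorm(n, 0, cfg$ki67$sd)
  ki67 <- 100 * stats::plogis(eta)
  clinical <- data.frame(sample_id = ids, arm = arm, rcb_class = rcb,
                         ki67_post_pct = ki67, time_years = time,
                         event = event, er_ihc = "pos", her2_ihc = "neg",
                         esr1_log2fpkm = NA_real_,
                         erbb2_log2fpkm = NA_real_,
                         stringsAsFactors = FALSE)

  # mutations: named driver genes at planted frequencies, passenger
  # records filling the negative-binomial burden, plus non-coding decoys
  recs <- list()
  named_genes <- rownames(cfg$mut_freq)
  sg_chr <- as.character(subgroup)
  flags <- matrix(stats::runif(length(named_genes) * n), length(named_genes),
                  n) < cfg$mut_freq[, sg_chr, drop = FALSE]
  tmb <- stats::rnbinom(n, mu = cfg$tmb_mean[sg_chr], size = cfg$tmb_size)
  passenger_pool <- sprintf("PSG%03d", 1:300)
  for (i in seq_len(n)) {
    g_named <- named_genes[flags[, i]]
    n_pass <- max(0L, tmb[i] - length(g_named))
    g_pass <- sample(passenger_pool, n_pass, replace = TRUE)
    cls_pass <- sample(c("Missense_Mutation", "Silent",
                         "Nonsense_Mutation", "Frame_Shift_Del"),
                       n_pass, replace = TRUE,
                       prob = c(0.6, 0.25, 0.1, 0.05))
    n_nc <- stats::rpois(1, 0.1 * max(tmb[i], 1))
    g_nc <- sample(passenger_pool, n_nc, replace = TRUE)
    recs[[i]] <- data.frame(
      sample_id = ids[i],
      gene = c(g_named, g_pass, g_nc),
      variant_classification = c(rep("Missense_Mutation",
                                     length(g_named)), cls_pass,
                                 sample(c("Intron", "3'UTR"), n_nc,
                                        replace = TRUE)),
      stringsAsFactors = FALSE)
  }
  mutations <- do.call(rbind, recs)
  rownames(mutations) <- NULL

  truth <- data.frame(sample_id = ids, m = m, e = e,
                      subgroup = as.character(subgroup), arm = arm,
                      p_pcr = p_pcr, stringsAsFactors = FALSE)
  structure(list(expression = emat, clinical = clinical,
                 mutations = mutations, truth = truth, config = cfg),
            class = "synthetic_cohort")
}

#' Write a synthetic cohort to disk
#'
#' Emits the same dialects the pipeline readers accept: expression TSV,
#' clinical CSV, MAF-style mutation TSV, a truth TSV and a provenance JSON
#' echoing the seed and configuration.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression_tsv(cohort$expression, file.path(dir, "expression.tsv"))
  utils::write.csv(cohort$clinical, file.path(dir, "clinical.csv"),
                   row.names = FALSE)
  maf <- data.frame(Tumor_Sample_Barcode = cohort$mutations$sample_id,
                    Hugo_Symbol = cohort$mutations$gene,
                    Variant_Classification =
                      cohort$mutations$variant_classification)
  utils::write.table(maf, file.path(dir, "mutations.maf.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- unclass(cohort$config)
  cfg$pcr_prob <- as.data.frame(cfg$pcr_prob)
  cfg$mut_freq <- as.data.frame(cfg$mut_freq)
  jsonlite::write_json(cfg, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

# check that rounded rate reconstruction matches a printed percentage
assert_printed_rate <- function(x, n, printed_pct) {
  if (abs(round(100 * x / n, 1) - printed_pct) > 0.05)
    stop(sprintf("fixture reconstruction %d/%d does not reproduce the %.1f%% rate",
                 x, n, printed_pct))
  invisible(TRUE)
}

#' Deterministic neoadjuvant immunotherapy trial fixture
#'
#' The two 2 x 2 pCR tables of an I-SPY2-style ER+/HER2- cohort, one per
#' ERS stratum, with cell counts reconstructed from the printed arm sizes
#' and response rates (ERS-low: 10/24 with pembrolizumab vs 9/43 without;
#' ERS-high: 2/16 vs 5/51), plus a per-patient clinical table carrying the
#' same counts.  Reconstruction is asserted to reproduce the printed rates
#' (41.7/20.9 and 12.5/9.8 percent) to one decimal at build time.
#'
#' @return List with elements `erslo` and `ershi` (each a named vector
#'   `a`, `b`, `c`, `d`: responders/non-responders in the experimental
#'   then control arm) and `clinical` (data.frame with `sample_id`, `arm`,
#'   `ers`, `rcb_class`).
#' @export
make_ispy2_fixture <- function() {
  erslo <- c(a = 10L, b = 14L, c = 9L, d = 34L)
  ershi <- c(a = 2L, b = 14L, c = 5L, d = 46L)
  assert_printed_rate(10, 24, 41.7)
  assert_printed_rate(9, 43, 20.9)
  assert_printed_rate(2, 16, 12.5)
  assert_printed_rate(5, 51, 9.8)
  strata <- rbind(
    data.frame(ers = "ERSlo", arm = "chemo_pembro",
               pcr = rep(c(TRUE, FALSE), c(10, 14))),
    data.frame(ers = "ERSlo", arm = "chemo",
               pcr = rep(c(TRUE, FALSE), c(9, 34))),
    data.frame(ers = "ERShi", arm = "chemo_pembro",
               pcr = rep(c(TRUE, FALSE), c(2, 14))),
    data.frame(ers = "ERShi", arm = "chemo",
               pcr = rep(c(TRUE, FALSE), c(5, 46))))
  clinical <- data.frame(sample_id = sprintf("ISPY%03d",
                                             seq_len(nrow(strata))),
                         arm = strata$arm, ers = strata$ers,
                         rcb_class = ifelse(strata$pcr, "0", "II"),
                         stringsAsFactors = FALSE)
  list(erslo = erslo, ershi = ershi, clinical = clinical)
}

#' Deterministic neoadjuvant endocrine therapy fixture
#'
#' Post-treatment Ki67 values for the two highly proliferative subgroups
#' of a POETIC-style cohort: exactly 21 of 42 MKShi_ERSlo samples and 10
#' of 41 MKShi_ERShi samples have Ki67 above 10 percent (endocrine
#' non-response); the remainder lie below.
#'
#' @return data.frame with `sample_id`, `subgroup`, `ki67_post_pct`.
#' @export
make_poetic_fixture <- function() {
  vals <- function(n_high, n_low) {
    c(seq(12, 60, length.out = n_high), seq(0.5, 9, length.out = n_low))
  }
  df <- rbind(
    data.frame(subgroup = "MKShi_ERSlo", ki67_post_pct = vals(21, 21)),
    data.frame(subgroup = "MKShi_ERShi", ki67_post_pct = vals(10, 31)))
  df$sample_id <- sprintf("POETIC%03d", seq_len(nrow(df)))
  assert_printed_rate(21, 42, 50.0)
  assert_printed_rate(10, 41, 24.4)
  df[, c("sample_id", "subgroup", "ki67_post_pct")]
}
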