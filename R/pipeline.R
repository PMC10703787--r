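PIPELINE_CONFIG_KEYS <- c("expression", "platform", "clinical",
                          "mutations", "gene_sets", "mode", "thresholds",
                          "tie", "alpha", "out_dir", "seed", "horizon")

#' Validate a pipeline run configuration
#'
#' A configuration is a named list (or a path to a JSON file holding one)
#' with keys: `expression` (TSV path, required), `platform`, `clinical`
#' (CSV path), `mutations` (MAF TSV path), `gene_sets` (panel GMT path),
#' `mode` (`"four_group"`/`"ers_only"`), `thresholds` (list with `source`
#' and, for predefined cuts, `mks_cut`/`ers_cut`), `tie`, `alpha`,
#' `out_dir` (required), `seed`, `horizon` (years, for the survival-rate
#' summary).  Unknown keys are rejected.
#'
#' @param config named list or JSON path.
#' @return The validated, default-filled configuration list.
#' @export
validate_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), PIPELINE_CONFIG_KEYS)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (key in c("expression", "out_dir"))
    if (is.null(config[[key]])) stop("config key '", key, "' is required")
  defaults <- list(platform = "generic", mode = "four_group", tie = "low",
                   alpha = 0.05, seed = 1L, horizon = 4,
                   thresholds = list(source = "cohort_median"))
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  config$mode <- match.arg(config$mode, c("four_group", "ers_only"))
  for (key in c("expression", "clinical", "mutations", "gene_sets")) {
    if (!is.null(config[[key]]) && !file.exists(config[[key]]))
      stop("config input not readable: ", key, " = ", config[[key]])
  }
  config
}

#' Run the stratification pipeline end to end
#'
#' Stage order: impute missing expression, resolve and filter signature
#' features, score the MKS/ERS metagenes (and any biomarker panel),
#' classify samples into subgroups, then — when the corresponding inputs
#' are present — compute mutational burden and per-gene frequency tests,
#' and run the standard outcome comparisons (response odds ratios by arm
#' within each subgroup; Kaplan-Meier, log-rank and univariate Cox between
#' the two highly proliferative subgroups).  All thresholds actually used
#' (median cut-offs, probe exclusions) are logged into the provenance
#' file, so classification is auditable.  Identical configuration and
#' inputs yield identical outputs.
#'
#' @param config see [validate_run_config()].
#' @return Invisibly, the result bundle: list with `scores`, `labels`,
#'   `thresholds`, `tmb`, `gene_tests`, `comparisons`, `provenance`.
#'   Side effect: writes `scores.tsv`, `labels.tsv`, `tmb.tsv`,
#'   `gene_frequency_tests.tsv`, `comparisons.json` and `provenance.json`
#'   under `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_run_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(cfg$seed)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  mat <- stage("read_expression",
               read_expression_tsv(cfg$expression, platform = cfg$platform))
  mat <- stage("impute", impute_missing(mat))

  sigs <- list(MKS = mks_signature(), ERS = ers_signature())
  if (!is.null(cfg$gene_sets)) sigs <- c(sigs, read_gmt(cfg$gene_sets))
  feature_log <- list()
  scores <- list()
  nfeat <- integer(0)
  for (nm in names(sigs)) {
    sig <- sigs[[nm]]
    feats <- tryCatch(resolve_features(sig, mat), error = function(e) NULL)
    if (is.null(feats)) {
      warning("signature unrepresented, skipped: ", nm)
      next
    }
    kept <- if (length(feats) > 1L)
      stage("filter_probes", filter_discordant_probes(mat, feats))
    else feats
    feature_log[[nm]] <- list(resolved = feats,
                              excluded = setdiff(feats, kept))
    scores[[nm]] <- stage("score", score_metagene(mat, sig, kept))
    nfeat[nm] <- length(kept)
  }
  if (is.null(scores$ERS)) stop("pipeline requires the ERS signature")
  score_df <- data.frame(sample_id = colnames(mat$values),
                         as.data.frame(scores), check.names = FALSE)

  thr_cfg <- cfg$thresholds
  thr <- stage("thresholds", if (identical(thr_cfg$source, "predefined"))
    make_thresholds(mks_cut = thr_cfg$mks_cut, ers_cut = thr_cfg$ers_cut,
                    source = "predefined")
  else
    make_thresholds(mks = scores$MKS, ers = scores$ERS))
  labels <- stage("classify",
                  assign_subgroups(scores$MKS, scores$ERS, thr,
                                   mode = cfg$mode, tie = cfg$tie))
  label_df <- data.frame(sample_id = score_df$sample_id,
                         mks_score = if (is.null(scores$MKS)) NA_real_
                                     else scores$MKS,
                         ers_score = scores$ERS,
                         subgroup = as.character(labels),
                         mks_cut = thr$mks_cut, ers_cut = thr$ers_cut,
                         threshold_source = thr$source,
                         stringsAsFactors = FALSE)

  clinical <- if (!is.null(cfg$clinical))
    utils::read.csv(cfg$clinical, stringsAsFactors = FALSE) else NULL
  if (!is.null(clinical)) {
    clinical <- merge(label_df[, c("sample_id", "subgroup")], clinical,
                      by = "sample_id", sort = TRUE)
  }

  tmb <- gene_tests <- NULL
  if (!is.null(cfg$mutations)) {
    muts <- stage("read_mutations", read_maf(cfg$mutations))
    samples <- label_df$sample_id
    tmb <- stage("tmb", compute_tmb(muts, samples))
    lab_vec <- stats::setNames(label_df$subgroup, label_df$sample_id)
    top <- stage("top_genes", top_mutated_genes(muts, samples))
    gene_tests <- stage("frequency_tests",
                        frequency_table_and_test(muts, lab_vec,
                                                 top$gene))
  }

  comparisons <- list()
  if (!is.null(clinical) && "rcb_class" %in% names(clinical) &&
      "arm" %in% names(clinical) &&
      length(unique(stats::na.omit(clinical$arm))) == 2L) {
    resp <- classify_pathological_response(clinical$rcb_class)
    arms <- sort(unique(clinical$arm))  # second level = experimental
    for (sg in unique(stats::na.omit(clinical$subgroup))) {
      sel <- clinical$subgroup == sg & !is.na(resp$pcr)
      t2 <- table(factor(clinical$arm[sel], levels = rev(arms)),
                  factor(resp$pcr[sel], levels = c(TRUE, FALSE)))
      if (any(rowSums(t2) == 0)) next
      or <- tryCatch(
        midp_median_unbiased_or(t2[1, 1], t2[1, 2], t2[2, 1], t2[2, 2],
                                alpha = cfg$alpha),
        error = function(e) {
          warning("odds ratio skipped for subgroup ", sg, ": ",
                  conditionMessage(e))
          NULL
        })
      if (is.null(or)) next
      comparisons[[paste0("pcr_or_", sg)]] <-
        list(type = "response_odds_ratio", endpoint = "pcr",
             subgroup = sg, exposed_arm = arms[2], reference_arm = arms[1],
             estimate = or$psi_hat, ci_low = or$ci_low,
             ci_high = or$ci_high, alpha = or$alpha, method = or$method,
             n_exposed = sum(t2[1, ]), n_reference = sum(t2[2, ]))
    }
  }
  if (!is.null(clinical) && all(c("time_years", "event") %in%
                                names(clinical))) {
    pair <- c("MKShi_ERShi", "MKShi_ERSlo")
    sel <- clinical$subgroup %in% pair
    if (sum(sel) > 3 && length(unique(clinical$subgroup[sel])) == 2L) {
      lr <- logrank_test(clinical$time_years[sel], clinical$event[sel],
                         clinical$subgroup[sel])
      cx <- cox_univariate(clinical$time_years[sel], clinical$event[sel],
                           factor(clinical$subgroup[sel], levels = pair))
      km <- km_estimate(clinical$time_years[sel], clinical$event[sel],
                        clinical$subgroup[sel])
      comparisons$defs_mkshi <- list(
        type = "survival", groups = pair,
        surv_at_horizon = stats::setNames(
          lapply(pair, function(g)
            km_survival_at(km, cfg$horizon, group = g)), pair),
        horizon_years = cfg$horizon,
        logrank_statistic = lr$statistic, logrank_df = lr$df,
        logrank_p = lr$p_value, cox_hr = cx$hr, cox_ci_low = cx$ci_low,
        cox_ci_high = cx$ci_high, cox_p = cx$p_value)
    }
  }

  provenance <- list(
    package_version = as.character(utils::packageVersion("mksers")),
    config = cfg, config_hash = config_hash(cfg),
    thresholds = thr, n_features_used = as.list(nfeat),
    features = feature_log,
    subgroup_counts = as.list(table(label_df$subgroup)))

  utils::write.table(score_df, file.path(cfg$out_dir, "scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(label_df, file.path(cfg$out_dir, "labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(tmb))
    utils::write.table(data.frame(sample_id = names(tmb), tmb = tmb),
                       file.path(cfg$out_dir, "tmb.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(gene_tests)) {
    out <- cbind(gene_tests$tests,
                 as.data.frame(gene_tests$frequencies))
    utils::write.table(out,
                       file.path(cfg$out_dir,
                                 "gene_frequency_tests.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(comparisons,
                       file.path(cfg$out_dir, "comparisons.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(provenance,
                       file.path(cfg$out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)

  invisible(list(scores = score_df, labels = label_df, thresholds = thr,
                 tmb = tmb, gene_tests = gene_tests,
                 comparisons = comparisons, provenance = provenance))
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg[order(names(cfg))], tmp, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}
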