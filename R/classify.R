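#' Cohort-median threshold for a score vector
#'
#' The classification threshold is the cohort-specific sample median (the
#' midpoint of the two central order statistics for even n).
#'
#' @param scores numeric vector; needs at least 2 finite values.
#' @return The median, a length-1 numeric.
#' @export
median_threshold <- function(scores) {
  s <- scores[is.finite(scores)]
  if (length(s) < 2L) stop("need >= 2 finite scores for a median threshold")
  stats::median(s)
}

SUBGROUP_LEVELS <- c("MKSlo_ERShi", "MKSlo_ERSlo", "MKShi_ERShi",
                     "MKShi_ERSlo")
ERS_ONLY_LEVELS <- c("ERShi", "ERSlo")

#' Assign MKS/ERS subgroup labels
#'
#' A sample is "high" on a score iff the score is strictly above the cut;
#' scores equal to the cut are "low" (so "high" always means strictly above
#' a median threshold).  In `ers_only` mode the MKS score is ignored and
#' samples split into ERShi / ERSlo only — the mode used for cohorts known
#' a priori to be uniformly highly proliferative.
#'
#' @param mks,ers aligned numeric score vectors (`mks` may be `NULL` in
#'   `ers_only` mode).
#' @param thresholds list with elements `mks_cut`, `ers_cut` and optional
#'   `source`; see [make_thresholds()].
#' @param mode `"four_group"` or `"ers_only"`.
#' @param tie one of `"low"` (default) or `"high"`: which side a score
#'   exactly at the cut falls on.
#' @return Factor of subgroup labels (NA score gives NA label, with a
#'   warning).
#' @export
assign_subgroups <- function(mks, ers, thresholds,
                             mode = c("four_group", "ers_only"),
                             tie = c("low", "high")) {
  mode <- match.arg(mode)
  tie <- match.arg(tie)
  hi <- function(x, cut) if (tie == "low") x > cut else x >= cut
  ers_hi <- hi(ers, thresholds$ers_cut)
  if (mode == "ers_only") {
    if (anyNA(ers_hi)) warning("NA ERS score(s): NA label assigned")
    return(factor(ifelse(ers_hi, "ERShi", "ERSlo"),
                  levels = ERS_ONLY_LEVELS))
  }
  if (length(mks) != length(ers))
    stop("mks and ers score vectors must align")
  mks_hi <- hi(mks, thresholds$mks_cut)
  if (anyNA(mks_hi) || anyNA(ers_hi))
    warning("NA score(s): NA label assigned")
  lab <- paste0(ifelse(mks_hi, "MKShi", "MKSlo"), "_",
                ifelse(ers_hi, "ERShi", "ERSlo"))
  lab[is.na(mks_hi) | is.na(ers_hi)] <- NA
  factor(lab, levels = SUBGROUP_LEVELS)
}

#' Build classification thresholds
#'
#' Either cohort medians computed from the score vectors (the default rule)
#' or predefined cut-offs carried over from an external reference cohort.
#'
#' @param mks,ers score vectors (used when `source = "cohort_median"`).
#' @param mks_cut,ers_cut explicit cut-offs (used when
#'   `source = "predefined"`).
#' @param source `"cohort_median"` or `"predefined"`.
#' @return List with `mks_cut`, `ers_cut`, `source`.
#' @export
make_thresholds <- function(mks = NULL, ers = NULL, mks_cut = NULL,
                            ers_cut = NULL,
                            source = c("cohort_median", "predefined")) {
  source <- match.arg(source)
  if (source == "cohort_median") {
    list(mks_cut = if (is.null(mks)) NA_real_ else median_threshold(mks),
         ers_cut = median_threshold(ers), source = source)
  } else {
    stopifnot(is.finite(ers_cut))
    list(mks_cut = if (is.null(mks_cut)) NA_real_ else mks_cut,
         ers_cut = ers_cut, source = source)
  }
}

#' Assign ER and HER2 receptor status
#'
#' The pathology IHC call has priority; the mRNA rule is consulted only
#' where IHC is missing.  On the mRNA route, ER positivity is log2 FPKM of
#' ESR1 strictly greater than 2.145 and HER2 positivity log2 FPKM of ERBB2
#' strictly greater than 6.32.  Both sources missing gives NA.
#'
#' @param er_ihc,her2_ihc character vectors with values `"pos"`, `"neg"` or
#'   `NA`.
#' @param esr1_log2fpkm,erbb2_log2fpkm numeric log2 FPKM values or `NA`.
#' @param esr1_cut,erbb2_cut mRNA positivity cut-offs.
#' @return data.frame with columns `er_status` and `her2_status`
#'   (`"pos"`/`"neg"`/`NA`).
#' @export
assign_receptor_status <- function(er_ihc, her2_ihc,
                                   esr1_log2fpkm = NA_real_,
                                   erbb2_log2fpkm = NA_real_,
                                   esr1_cut = 2.145, erbb2_cut = 6.32) {
  call_one <- function(ihc, mrna, cut) {
    ihc <- as.character(ihc)
    out <- ihc
    use_mrna <- is.na(ihc) & !is.na(mrna)
    out[use_mrna] <- ifelse(mrna[use_mrna] > cut, "pos", "neg")
    out
  }
  n <- max(length(er_ihc), length(her2_ihc))
  data.frame(
    er_status = call_one(rep_len(er_ihc, n), rep_len(esr1_log2fpkm, n),
                         esr1_cut),
    her2_status = call_one(rep_len(her2_ihc, n), rep_len(erbb2_log2fpkm, n),
                           erbb2_cut),
    stringsAsFactors = FALSE)
}

#' Code pathological response from residual cancer burden class
#'
#' RCB 0 (pathological complete response) and RCB I (minimal residual
#' cancer) form the pathological-response group (pathR); RCB II and III
#' form the residual-disease group (RD).  The pCR flag is true only for
#' RCB 0.
#'
#' @param rcb_class character/factor vector with values `"0"`, `"I"`,
#'   `"II"`, `"III"` or `NA`.
#' @return data.frame with columns `response` (`"pathR"`/`"RD"`/`NA`) and
#'   `pcr` (logical).
#' @export
classify_pathological_response <- function(rcb_class) {
  rcb <- as.character(rcb_class)
  bad <- !is.na(rcb) & !rcb %in% c("0", "I", "II", "III")
  if (any(bad)) stop("invalid RCB class: ", paste(unique(rcb[bad]),
                                                  collapse = ", "))
  response <- ifelse(rcb %in% c("0", "I"), "pathR",
                     ifelse(rcb %in% c("II", "III"), "RD", NA))
  data.frame(response = response, pcr = !is.na(rcb) & rcb == "0",
             stringsAsFactors = FALSE)
}

#' Code endocrine response from post-treatment Ki67
#'
#' A post-treatment Ki67 percentage strictly below 10% counts as endocrine
#' response (a surrogate of long-term benefit); 10% or above is
#' non-response.  Exactly 10.0 therefore codes as non-responder.
#'
#' @param ki67_post_pct numeric percentages in \[0, 100\] or `NA`.
#' @param cut response threshold in percent, default 10.
#' @return Character vector `"responder"` / `"non_responder"` / `NA`.
#' @export
classify_ki67_response <- function(ki67_post_pct, cut = 10) {
  x <- as.numeric(ki67_post_pct)
  if (any(!is.na(x) & (x < 0 | x > 100)))
    stop("Ki67 percentages must lie in [0, 100]")
  ifelse(is.na(x), NA_character_,
         ifelse(x < cut, "responder", "non_responder"))
}
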