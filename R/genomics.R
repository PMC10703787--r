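# MAF Variant_Classification vocabulary split into the coding classes that
# count toward mutational burden (synonymous and non-synonymous exonic
# variants) and the non-coding classes that do not.
CODING_CLASSES <- c("Missense_Mutation", "Nonsense_Mutation",
                    "Nonstop_Mutation", "Silent", "Splice_Site",
                    "Frame_Shift_Ins", "Frame_Shift_Del", "In_Frame_Ins",
                    "In_Frame_Del", "Translation_Start_Site")
NONCODING_CLASSES <- c("Intron", "3'UTR", "5'UTR", "3'Flank", "5'Flank",
                       "IGR", "RNA")

# recurrently mutated genes generally regarded as passengers, removed by
# default before ranking driver-gene frequencies
DEFAULT_NONDRIVER_GENES <- c("TTN", "MUC16", "MUC4", "OBSCN", "SYNE1",
                             "FLG", "HMCN1", "RYR2", "USH2A", "DNAH5",
                             "GPR98", "XIRP2", "PCLO", "CSMD1", "CSMD3")

#' Read a MAF-like somatic mutation table
#'
#' Accepts the standard MAF column names `Tumor_Sample_Barcode`,
#' `Hugo_Symbol` and `Variant_Classification` (or lower-case `sample_id`,
#' `gene`, `variant_classification`).
#'
#' @param path TSV path.
#' @return data.frame with columns `sample_id`, `gene`,
#'   `variant_classification`.
#' @export
read_maf <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  pick <- function(...) {
    for (nm in c(...)) if (nm %in% names(df)) return(df[[nm]])
    stop("MAF table lacks a required column (tried: ",
         paste(c(...), collapse = ", "), ")")
  }
  data.frame(sample_id = as.character(pick("Tumor_Sample_Barcode",
                                           "sample_id")),
             gene = as.character(pick("Hugo_Symbol", "gene")),
             variant_classification = as.character(
               pick("Variant_Classification", "variant_classification")),
             stringsAsFactors = FALSE)
}

is_coding <- function(variant_classification,
                      on_unknown = c("warn", "error")) {
  on_unknown <- match.arg(on_unknown)
  known <- c(CODING_CLASSES, NONCODING_CLASSES)
  unknown <- setdiff(unique(variant_classification), known)
  if (length(unknown)) {
    msg <- paste("unknown variant classification(s):",
                 paste(unknown, collapse = ", "))
    if (on_unknown == "error") stop(msg)
    warning(msg, " — excluded from coding counts")
  }
  variant_classification %in% CODING_CLASSES
}

#' Tumour mutational burden per sample
#'
#' TMB is the raw count of synonymous plus non-synonymous coding mutations
#' in the exome (classes listed in the package's coding-class vocabulary;
#' intronic, UTR, flank, IGR and RNA records are excluded).  Samples not
#' present in the table get 0.
#'
#' @param muts mutation data.frame as from [read_maf()].
#' @param samples character vector of sample IDs to report.
#' @param on_unknown `"warn"` (exclude with a warning) or `"error"` for
#'   variant classifications outside the documented vocabulary.
#' @return Named integer vector of mutation counts.
#' @export
compute_tmb <- function(muts, samples = sort(unique(muts$sample_id)),
                        on_unknown = c("warn", "error")) {
  keep <- is_coding(muts$variant_classification, on_unknown)
  counts <- table(factor(muts$sample_id[keep], levels = samples))
  out <- as.integer(counts)
  names(out) <- samples
  out
}

#' Rank the most frequently mutated genes
#'
#' Genes are ranked by the fraction of samples carrying at least one coding
#' mutation, after dropping an exclusion list of recurrent non-driver
#' genes.  Ties break alphabetically.
#'
#' @param muts mutation data.frame.
#' @param samples sample universe (denominator of the frequencies).
#' @param k number of genes to return (top 15 by default).
#' @param exclusion genes removed before ranking; defaults to a bundled
#'   list of recurrent passenger genes.
#' @return data.frame with columns `gene`, `n_mutated`, `frequency`,
#'   ordered by decreasing frequency; at most `k` rows.
#' @export
top_mutated_genes <- function(muts, samples = sort(unique(muts$sample_id)),
                              k = 15L,
                              exclusion = DEFAULT_NONDRIVER_GENES) {
  stopifnot(k >= 1L)
  keep <- is_coding(muts$variant_classification) &
    muts$sample_id %in% samples & !(muts$gene %in% exclusion)
  m <- unique(muts[keep, c("sample_id", "gene")])
  if (nrow(m) == 0L)
    return(data.frame(gene = character(0), n_mutated = integer(0),
                      frequency = numeric(0)))
  counts <- table(m$gene)
  df <- data.frame(gene = names(counts), n_mutated = as.integer(counts),
                   stringsAsFactors = FALSE)
  df$frequency <- df$n_mutated / length(samples)
  df <- df[order(-df$frequency, df$gene), , drop = FALSE]
  rownames(df) <- NULL
  utils::head(df, k)
}

# generalized Cochran-Mantel-Haenszel statistic for a single-stratum 2 x G
# table: the (n-1)/n scaled Pearson chi-square (general association, df G-1)
cmh_single_stratum <- function(tab) {
  n <- sum(tab)
  if (n == 0 || any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(statistic = 0, df = ncol(tab) - 1L, p.value = 1))
  st <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  stat <- unname(st$statistic) * (n - 1) / n
  df <- ncol(tab) - 1L
  list(statistic = stat, df = df,
       p.value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Mutation frequencies by subgroup with CMH tests
#'
#' For each gene, tabulates mutated vs wild-type across the subgroups and
#' tests the frequency distribution with the Cochran-Mantel-Haenszel
#' chi-square (general association, df = G - 1).  Without a stratification
#' variable the statistic is the single-stratum form, the (n-1)/n scaled
#' Pearson chi-square; with `stratum` supplied the fully stratified
#' generalized CMH test is used.
#'
#' @param muts mutation data.frame.
#' @param labels subgroup label per sample: a factor/character vector named
#'   by sample ID, or aligned with `samples`.
#' @param genes genes to test.
#' @param samples sample universe; defaults to `names(labels)`.
#' @param stratum optional stratification factor aligned with `samples`.
#' @return List with `frequencies` (gene x subgroup proportion matrix),
#'   `counts` (gene x subgroup mutated counts), `tests` (data.frame gene,
#'   statistic, df, p_value, note).
#' @export
frequency_table_and_test <- function(muts, labels, genes,
                                     samples = names(labels),
                                     stratum = NULL) {
  if (is.null(samples))
    stop("supply `samples` or a named `labels` vector")
  labels <- factor(as.character(labels))
  labels <- droplevels(labels)
  if (nlevels(labels) < 2L) stop("need >= 2 subgroups")
  if (length(labels) != length(samples))
    stop("labels must align with samples")
  keep <- is_coding(muts$variant_classification) &
    muts$sample_id %in% samples
  m <- unique(muts[keep, c("sample_id", "gene")])
  grp_n <- table(labels)
  freqs <- counts <- matrix(0, nrow = length(genes),
                            ncol = nlevels(labels),
                            dimnames = list(genes, levels(labels)))
  tests <- data.frame(gene = genes, statistic = NA_real_,
                      df = nlevels(labels) - 1L, p_value = NA_real_,
                      note = "", stringsAsFactors = FALSE)
  for (i in seq_along(genes)) {
    g <- genes[i]
    mutated_samples <- m$sample_id[m$gene == g]
    mut <- samples %in% mutated_samples
    counts[i, ] <- tapply(mut, labels, sum)
    freqs[i, ] <- counts[i, ] / as.numeric(grp_n)
    if (!any(mut)) {
      tests$note[i] <- "gene absent from mutation table; test skipped"
      next
    }
    tab <- rbind(mutated = counts[i, ],
                 wildtype = as.numeric(grp_n) - counts[i, ])
    if (is.null(stratum) || nlevels(factor(stratum)) < 2L) {
      res <- cmh_single_stratum(tab)
    } else {
      arr <- table(factor(ifelse(mut, "mutated", "wildtype"),
                          levels = c("mutated", "wildtype")),
                   labels, factor(stratum))
      res <- stats::mantelhaen.test(arr, correct = FALSE)
      res <- list(statistic = unname(res$statistic),
                  df = unname(res$parameter), p.value = res$p.value)
    }
    tests$statistic[i] <- res$statistic
    tests$df[i] <- res$df
    tests$p_value[i] <- res$p.value
  }
  list(frequencies = freqs, counts = counts, tests = tests)
}
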