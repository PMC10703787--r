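#' Expression matrix container
#'
#' A light wrapper around a numeric features x samples matrix of log-scale
#' expression values.  Missing values are carried as `NA`.  The `platform`
#' tag records the measurement technology: tags beginning with `"affy"`
#' mark Affymetrix arrays whose row names are probe-set IDs (signatures are
#' then resolved by probe ID); any other tag is treated as gene-symbol
#' indexed.  Platforms tagged `"*_linear"` are log2(x+1)-transformed on
#' construction so that all downstream scoring operates on a log2 scale.
#'
#' @param values numeric matrix, features in rows, samples in columns.
#' @param feature_ids,sample_ids optional character vectors overriding the
#'   dimnames of `values`; must be unique.
#' @param platform character tag, e.g. `"affy_hgu133a"`, `"rnaseq_log2fpkm"`,
#'   `"rnaseq_linear"`.
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   (named numeric matrix) and `platform`.
#' @export
expr_matrix <- function(values, feature_ids = rownames(values),
                        sample_ids = colnames(values),
                        platform = "generic") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(feature_ids) || is.null(sample_ids))
    stop("expression matrix needs feature and sample identifiers")
  feature_ids <- as.character(feature_ids)
  sample_ids <- as.character(sample_ids)
  if (length(feature_ids) != nrow(values) || length(sample_ids) != ncol(values))
    stop("identifier lengths inconsistent with matrix dimensions")
  if (anyDuplicated(feature_ids)) stop("duplicate feature identifiers")
  if (anyDuplicated(sample_ids)) stop("duplicate sample identifiers")
  dimnames(values) <- list(feature_ids, sample_ids)
  if (grepl("_linear$", platform)) {
    values <- log2(values + 1)
    platform <- sub("_linear$", "_log2", platform)
  }
  structure(list(values = values, platform = platform),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d features x %d samples [%s], %d missing\n",
              nrow(x$values), ncol(x$values), x$platform,
              sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

is_affymetrix <- function(mat) grepl("^affy", mat$platform)

#' Read an expression matrix from delimited text
#'
#' Expects a TSV with the feature identifier in the first column and sample
#' identifiers in the header row.  Empty cells and `NA` are read as missing.
#'
#' @param path file path.
#' @param platform platform tag, see [expr_matrix()].
#' @return An `expr_matrix`.
#' @export
read_expression_tsv <- function(path, platform = "generic") {
  df <- utils::read.delim(path, check.names = FALSE, na.strings = c("NA", ""),
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  expr_matrix(m, feature_ids = df[[1]], sample_ids = colnames(df)[-1],
              platform = platform)
}

#' Write an expression matrix as TSV
#'
#' @param mat an `expr_matrix`.
#' @param path output file path.
#' @export
write_expression_tsv <- function(mat, path) {
  df <- data.frame(feature_id = rownames(mat$values), mat$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Impute missing expression values with the matrix minimum
#'
#' Every missing entry is replaced by the lowest observed value anywhere in
#' the matrix (the imputation rule used for panel-array cohorts with
#' below-detection dropouts); observed values are untouched.
#'
#' @param mat an `expr_matrix`.
#' @return The imputed `expr_matrix`, with no missing values.
#' @export
impute_missing <- function(mat) {
  stopifnot(inherits(mat, "expr_matrix"))
  v <- mat$values
  if (all(is.na(v))) stop("cannot impute an all-missing matrix")
  if (!anyNA(v)) return(mat)
  v[is.na(v)] <- min(v, na.rm = TRUE)
  mat$values <- v
  mat
}
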