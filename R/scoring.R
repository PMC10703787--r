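#' Resolve signature members to matrix features
#'
#' On Affymetrix-tagged platforms (platform starting `"affy"`) members are
#' matched by probe-set ID; on every other platform by gene symbol,
#' case-insensitively.  All matrix features matching a member are returned
#' (several probes may target one gene), in signature order, then feature
#' order within a member.
#'
#' @param signature a `gene_signature`.
#' @param matrix an `expr_matrix`.
#' @return Character vector of matched feature IDs.
#' @export
resolve_features <- function(signature, matrix) {
  stopifnot(inherits(signature, "gene_signature"),
            inherits(matrix, "expr_matrix"))
  feats <- rownames(matrix$values)
  if (length(feats) == 0L) stop("empty expression matrix")
  hits <- if (is_affymetrix(matrix)) {
    lapply(signature$probe_ids, function(p) {
      if (is.na(p)) character(0) else feats[feats == p]
    })
  } else {
    lapply(signature$symbols,
           function(s) feats[toupper(feats) == toupper(s)])
  }
  out <- unique(unlist(hits))
  if (length(out) == 0L)
    stop("signature unrepresented: no features of '", signature$name,
         "' found in the matrix")
  out
}

#' Drop probes discordant with the dominant expression cluster
#'
#' When several probes target a metagene's members, probes that do not track
#' the common signal inflate noise or even point the wrong way.  Candidates
#' are clustered by average linkage on the distance 1 - r (pairwise Pearson
#' correlation across samples); the dendrogram is cut at height 1 - r_min
#' and the largest resulting cluster is retained (ties go to the cluster
#' containing the lexicographically smallest feature ID).  Zero-variance
#' candidates cannot enter a correlation and are excluded beforehand with a
#' warning.
#'
#' @param matrix an `expr_matrix`.
#' @param candidate_features feature IDs to filter (at least 2).
#' @param r_min correlation threshold; probes correlating below this with
#'   the dominant cluster are excluded.  Default 0.4.
#' @return Retained feature IDs, in candidate order.
#' @export
filter_discordant_probes <- function(matrix, candidate_features,
                                     r_min = 0.4) {
  stopifnot(inherits(matrix, "expr_matrix"))
  cand <- as.character(candidate_features)
  missing <- setdiff(cand, rownames(matrix$values))
  if (length(missing))
    stop("candidate features absent from matrix: ",
         paste(missing, collapse = ", "))
  if (length(cand) < 2L) stop("need at least 2 candidate features")
  x <- matrix$values[cand, , drop = FALSE]
  n_obs <- rowSums(!is.na(x))
  if (any(n_obs < 3L))
    stop("each candidate needs >= 3 non-missing samples")
  v <- apply(x, 1L, stats::var, na.rm = TRUE)
  degenerate <- !is.finite(v) | v == 0
  if (any(degenerate)) {
    warning("degenerate variance: excluding zero-variance feature(s) ",
            paste(cand[degenerate], collapse = ", "))
    cand <- cand[!degenerate]
    x <- x[cand, , drop = FALSE]
  }
  if (length(cand) < 2L) return(cand)
  r <- stats::cor(t(x), use = "pairwise.complete.obs")
  d <- stats::as.dist(1 - r)
  hc <- stats::hclust(d, method = "average")
  cl <- stats::cutree(hc, h = 1 - r_min)
  sizes <- table(cl)
  big <- as.integer(names(sizes)[sizes == max(sizes)])
  if (length(big) > 1L) {
    # tie-break: the cluster holding the lexicographically smallest ID
    first <- vapply(big, function(k) min(sort(cand[cl == k])), "")
    big <- big[order(first)[1L]]
  }
  cand[cl == big]
}

#' Compute a per-sample metagene score
#'
#' The score is the (weighted) arithmetic mean of log-scale expression over
#' the given features, with missing entries handled by the within-sample
#' mean of the available features.  `single_gene` signatures return the
#' feature's row unchanged.
#'
#' @param matrix an `expr_matrix`.
#' @param signature a `gene_signature` (supplies weights and aggregation).
#' @param features feature IDs, typically from [resolve_features()]
#'   followed by [filter_discordant_probes()].
#' @return Named numeric vector, one score per sample.
#' @export
score_metagene <- function(matrix, signature,
                           features = resolve_features(signature, matrix)) {
  stopifnot(inherits(matrix, "expr_matrix"),
            inherits(signature, "gene_signature"))
  x <- matrix$values[features, , drop = FALSE]
  w <- feature_weights(signature, matrix, features)
  W <- matrix(w, nrow = length(features), ncol = ncol(x))
  W[is.na(x)] <- 0
  x[is.na(x)] <- 0
  denom <- colSums(W)
  if (any(denom == 0))
    stop("all signature features missing for sample(s): ",
         paste(colnames(x)[denom == 0], collapse = ", "))
  colSums(x * W) / denom
}

# map member weights onto resolved features (several probes inherit the
# weight of the member they target)
feature_weights <- function(signature, matrix, features) {
  if (all(signature$weights == 1)) return(rep(1, length(features)))
  idx <- if (is_affymetrix(matrix)) {
    match(features, signature$probe_ids)
  } else {
    sym <- vapply(features, function(f) {
      hit <- which(toupper(signature$symbols) == toupper(f))
      if (length(hit)) hit[1L] else NA_integer_
    }, 1L)
    sym
  }
  if (anyNA(idx)) stop("cannot map features back to signature members")
  signature$weights[idx]
}

#' Score a panel of signatures
#'
#' For each signature: resolve features, filter discordant probes (only
#' when more than one feature matched), and compute the metagene score.
#' A signature with no matching features is recorded as unrepresented and
#' skipped rather than failing the whole panel.
#'
#' @param matrix an `expr_matrix`.
#' @param panel a list of `gene_signature` objects (e.g. from
#'   [read_gmt()]), or a single signature.
#' @param filter_probes apply [filter_discordant_probes()] when a signature
#'   resolves to more than one feature.  Default `TRUE`.
#' @param r_min correlation threshold passed to the probe filter.
#' @return A `score_table`: list with `sample_ids`, `scores` (named list of
#'   score vectors), `n_features_used` (named integer vector) and
#'   `unrepresented` (character vector of skipped signature names).
#' @export
score_panel <- function(matrix, panel, filter_probes = TRUE, r_min = 0.4) {
  if (inherits(panel, "gene_signature")) panel <- list(panel)
  scores <- list()
  nfeat <- integer(0)
  skipped <- character(0)
  for (sig in panel) {
    feats <- tryCatch(resolve_features(sig, matrix), error = function(e) {
      if (grepl("signature unrepresented", conditionMessage(e))) NULL
      else stop(e)
    })
    if (is.null(feats)) {
      warning("signature unrepresented, skipped: ", sig$name)
      skipped <- c(skipped, sig$name)
      next
    }
    if (filter_probes && length(feats) > 1L)
      feats <- filter_discordant_probes(matrix, feats, r_min = r_min)
    scores[[sig$name]] <- score_metagene(matrix, sig, feats)
    nfeat[sig$name] <- length(feats)
  }
  structure(list(sample_ids = colnames(matrix$values), scores = scores,
                 n_features_used = nfeat, unrepresented = skipped),
            class = "score_table")
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf("score_table: %d samples, signatures: %s\n",
              length(x$sample_ids),
              paste(sprintf("%s(%d)", names(x$scores), x$n_features_used),
                    collapse = ", ")))
  if (length(x$unrepresented))
    cat("unrepresented:", paste(x$unrepresented, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.score_table <- function(x, ...) {
  data.frame(sample_id = x$sample_ids, as.data.frame(x$scores),
             check.names = FALSE, row.names = NULL)
}
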