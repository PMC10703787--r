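#' Gene signature objects
#'
#' A `gene_signature` is a named gene list with optional platform probe IDs
#' and per-gene weights, plus an aggregation rule.  The two metagenes that
#' drive the stratification are shipped as [mks_signature()] (12 mitosis
#' kinases) and [ers_signature()] (4 estrogen-module genes); additional
#' biomarker panels load from GMT files via [read_gmt()].
#'
#' @param name signature name.
#' @param symbols character vector of gene symbols (HUGO).
#' @param probe_ids optional character vector of platform probe-set IDs,
#'   aligned with `symbols` (`NA` where unknown).
#' @param weights numeric weights, default 1 for every member.
#' @param aggregation one of `"mean"`, `"weighted_mean"`, `"single_gene"`.
#' @return An object of class `gene_signature`.
#' @export
gene_signature <- function(name, symbols, probe_ids = NULL, weights = NULL,
                           aggregation = c("mean", "weighted_mean",
                                           "single_gene")) {
  aggregation <- match.arg(aggregation)
  symbols <- as.character(symbols)
  if (length(symbols) == 0L) stop("signature '", name, "' has no members")
  if (is.null(probe_ids)) probe_ids <- rep(NA_character_, length(symbols))
  if (is.null(weights)) weights <- rep(1, length(symbols))
  if (length(probe_ids) != length(symbols) ||
      length(weights) != length(symbols))
    stop("probe_ids/weights must align with symbols")
  if (!all(is.finite(weights))) stop("non-finite signature weights")
  if (aggregation == "single_gene" && length(symbols) != 1L)
    stop("single_gene signatures have exactly one member")
  structure(list(name = name, symbols = symbols,
                 probe_ids = as.character(probe_ids), weights = weights,
                 aggregation = aggregation),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("gene_signature '%s': %d members, aggregation=%s\n",
              x$name, length(x$symbols), x$aggregation))
  invisible(x)
}

# 12 mitosis / spindle-checkpoint / G2-M kinases with their HG-U133A
# probe sets; the proliferation axis of the classification.
MKS_TABLE <- data.frame(
  symbol = c("PLK1", "CDK1", "BUB1B", "NEK2", "TTK", "MELK", "PLK4",
             "CHEK1", "AURKA", "AURKB", "BUB1", "PBK"),
  probe_id = c("202240_at", "203213_at", "203755_at", "204641_at",
               "204822_at", "204825_at", "204887_s_at", "205394_at",
               "208079_s_at", "209464_at", "209642_at", "219148_at"),
  stringsAsFactors = FALSE)

# 4 genes of the estrogen module; the endocrine-signalling axis.
ERS_TABLE <- data.frame(
  symbol = c("BCL2", "ESR1", "PGR", "SCUBE2"),
  probe_id = c("203685_at", "205225_at", "208305_at", "219197_s_at"),
  stringsAsFactors = FALSE)

#' Mitosis kinase score (MKS) signature
#'
#' Twelve kinases involved in mitosis, spindle checkpoint and the G2-M
#' transition, averaged (unweighted) on the log2 scale.  Probe-set IDs are
#' for the Affymetrix HG-U133A platform.
#' @return A `gene_signature` with 12 members.
#' @export
mks_signature <- function() {
  gene_signature("MKS", MKS_TABLE$symbol, MKS_TABLE$probe_id)
}

#' Estrogen-related score (ERS) signature
#'
#' BCL2, ESR1, PGR and SCUBE2 — the estrogen module — averaged (unweighted)
#' on the log2 scale.
#' @return A `gene_signature` with 4 members.
#' @export
ers_signature <- function() {
  gene_signature("ERS", ERS_TABLE$symbol, ERS_TABLE$probe_id)
}

#' Read gene signatures from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' members.  Members may carry extra fields separated by `|`:
#' `SYMBOL`, `SYMBOL|weight` (numeric second field), `SYMBOL|probe_id`, or
#' `SYMBOL|probe_id|weight`.  A set whose description contains
#' `aggregation=weighted_mean` (or whose members carry weights) is scored as
#' a weighted mean; single-member sets default to `single_gene`.
#'
#' @param path GMT file path.
#' @return A named list of `gene_signature` objects.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sigs <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stop("malformed GMT line: ", substr(ln, 1, 40))
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    parts <- strsplit(members, "|", fixed = TRUE)
    symbols <- vapply(parts, `[[`, "", 1L)
    probe_ids <- rep(NA_character_, length(parts))
    weights <- rep(1, length(parts))
    for (i in seq_along(parts)) {
      extra <- parts[[i]][-1]
      for (e in extra) {
        if (grepl("^-?[0-9.]+$", e)) weights[i] <- as.numeric(e)
        else probe_ids[i] <- e
      }
    }
    agg <- if (length(symbols) == 1L) "single_gene"
           else if (grepl("aggregation=weighted_mean", f[2]) ||
                    any(weights != 1)) "weighted_mean"
           else "mean"
    gene_signature(f[1], symbols, probe_ids, weights, agg)
  })
  names(sigs) <- vapply(sigs, `[[`, "", "name")
  sigs
}

#' Write gene signatures to a GMT file
#'
#' @param sigs a list of `gene_signature` objects.
#' @param path output path.
#' @param descriptions optional named character vector of set descriptions.
#' @export
write_gmt <- function(sigs, path, descriptions = NULL) {
  lines <- vapply(sigs, function(s) {
    memb <- s$symbols
    has_probe <- !is.na(s$probe_ids)
    memb[has_probe] <- paste(memb[has_probe], s$probe_ids[has_probe],
                             sep = "|")
    nonunit <- s$weights != 1
    memb[nonunit] <- paste(memb[nonunit], s$weights[nonunit], sep = "|")
    desc <- if (!is.null(descriptions) && s$name %in% names(descriptions))
      descriptions[[s$name]] else "na"
    if (s$aggregation == "weighted_mean")
      desc <- paste0(desc, " aggregation=weighted_mean")
    paste(c(s$name, desc, memb), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Load the default biomarker panel
#'
#' Reads the bundled panel gene sets: RBsig (Rb loss-of-function), IRPS
#' (interferon-related palbociclib resistance, 35 genes), CCNE1 (single
#' gene), the TILs metagene and the T-cell-inflamed GEP.  The bundled RBsig,
#' IRPS, TILs and GEP member lists are synthetic placeholders standing in
#' for the published signatures (which this package does not redistribute);
#' supply your own GMT to score the published gene lists.
#'
#' @param path GMT path; defaults to the bundled placeholder panel.
#' @return Named list of `gene_signature` objects.
#' @export
default_panel <- function(path = system.file("extdata",
                                             "panel_synthetic.gmt",
                                             package = "mksers")) {
  read_gmt(path)
}
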