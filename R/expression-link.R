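#' Link methylation probes with gene-level expression by gene symbol
#'
#' One output row per (methylation probe, gene) pair. Genes with
#' multiple expression values are collapsed by the duplicate policy
#' before linking; genes absent on either side are dropped and counted.
#'
#' @param beta_probes Data frame with `probe_id`, `beta` (the per-probe
#'   summary to carry, e.g. a group mean) and optionally more columns.
#' @param annotation Probe annotation with `probe_id`, `gene_symbol`.
#' @param expression Either a named numeric vector (gene -> value) or a
#'   data frame with `gene_symbol` and `value`.
#' @param duplicate_policy Collapse function for repeated gene symbols
#'   on the expression side; default `"median"`.
#' @return Linked data frame (probe_id, gene_symbol, beta, expression);
#'   attribute `n_dropped` counts unlinked genes.
#' @export
merge_by_gene <- function(beta_probes, annotation, expression,
                          duplicate_policy = c("median", "mean")) {
  duplicate_policy <- match.arg(duplicate_policy)
  fun <- match.fun(duplicate_policy)
  if (is.data.frame(expression)) {
    ev <- expression$value
    names(ev) <- expression$gene_symbol
  } else {
    ev <- expression
  }
  collapsed <- tapply(as.numeric(ev), names(ev), fun)
  genes <- annotation$gene_symbol[match(beta_probes$probe_id,
                                        annotation$probe_id)]
  common <- intersect(unique(genes), names(collapsed))
  if (!length(common)) stop("no genes shared between methylation and ",
                            "expression tables")
  keep <- genes %in% common
  linked <- data.frame(probe_id = beta_probes$probe_id[keep],
                       gene_symbol = genes[keep],
                       beta = beta_probes$beta[keep],
                       expression = as.numeric(collapsed[genes[keep]]),
                       stringsAsFactors = FALSE)
  attr(linked, "n_dropped") <- length(setdiff(names(collapsed), common)) +
    length(setdiff(unique(genes), common))
  linked
}

#' Equal-count methylation quartiles
#'
#' Assigns probes to four quartiles by rank of their (group-mean)
#' beta-value; quartile sizes differ by at most one and ties are broken
#' by stable probe-id order.
#'
#' @param beta Named numeric vector of per-probe beta summaries.
#' @return List with `quartile` (named integer vector 1-4) and
#'   `boundaries` (min/max beta per quartile).
#' @export
quartile_by_methylation <- function(beta) {
  if (length(beta) < 4L) stop("need at least 4 probes to quartile")
  ids <- names(beta)
  if (is.null(ids)) ids <- as.character(seq_along(beta))
  if (length(unique(beta)) == 1L) {
    warning("all beta values equal; quartile assignment by probe order")
  }
  ord <- order(beta, ids)
  n <- length(beta)
  q <- integer(n)
  q[ord] <- ceiling(seq_len(n) * 4 / n)
  names(q) <- ids
  boundaries <- t(sapply(1:4, function(k) {
    range(beta[q == k])
  }))
  dimnames(boundaries) <- list(paste0("Q", 1:4), c("min", "max"))
  list(quartile = q, boundaries = boundaries)
}

#' Expression summaries per methylation quartile
#'
#' @param linked Linked table from [merge_by_gene()].
#' @param quartiles Quartile assignment from [quartile_by_methylation()]
#'   (named by probe id).
#' @return Data frame per quartile: n, median, q25, q75, min, max of
#'   expression.
#' @export
expression_by_quartile <- function(linked, quartiles) {
  if (!nrow(linked)) stop("empty linked table")
  q <- quartiles$quartile[linked$probe_id]
  rows <- lapply(1:4, function(k) {
    e <- linked$expression[which(q == k)]
    if (!length(e)) {
      warning("quartile ", k, " empty after linking")
      return(data.frame(quartile = k, n = 0L, median = NA_real_,
                        q25 = NA_real_, q75 = NA_real_,
                        min = NA_real_, max = NA_real_))
    }
    qs <- stats::quantile(e, c(0.25, 0.75), names = FALSE)
    data.frame(quartile = k, n = length(e), median = stats::median(e),
               q25 = qs[1], q75 = qs[2], min = min(e), max = max(e))
  })
  do.call(rbind, rows)
}

#' Methylation change vs expression change concordance
#'
#' Sign convention: positive delta-beta = higher methylation in third
#' trimester; positive logFC = higher expression in first trimester. A
#' gene is concordant when both exceed their thresholds in the
#' methylation-up/expression-down sense (`delta_beta >= delta_cut` and
#' `logfc >= lfc_cut`) or in the mirrored sense with both signs flipped.
#'
#' @param differential `DifferentialResult` for first vs third trimester
#'   (delta relative to third).
#' @param annotation Probe annotation (for gene symbols).
#' @param logfc Named numeric vector of per-gene log fold changes
#'   (positive = higher in first trimester).
#' @param delta_cut Delta-beta threshold (default 0.2).
#' @param lfc_cut Log fold-change threshold (default 1.0, i.e. 2-fold).
#' @return List with `scatter` (gene, delta_beta, logfc, concordant) and
#'   `concordant` gene set; attribute `n_unlinked` counts genes missing
#'   on one side.
#' @export
delta_vs_logfc <- function(differential, annotation, logfc,
                           delta_cut = 0.2, lfc_cut = 1.0) {
  genes <- annotation$gene_symbol[match(differential$probe_id,
                                        annotation$probe_id)]
  have <- genes %in% names(logfc)
  scatter <- data.frame(gene_symbol = genes[have],
                        delta_beta = differential$delta_beta[have],
                        logfc = as.numeric(logfc[genes[have]]),
                        stringsAsFactors = FALSE)
  scatter$concordant <-
    (scatter$delta_beta >= delta_cut & scatter$logfc >= lfc_cut) |
    (scatter$delta_beta <= -delta_cut & scatter$logfc <= -lfc_cut)
  scatter$concordant[is.na(scatter$concordant)] <- FALSE
  out <- list(scatter = scatter,
              concordant = unique(scatter$gene_symbol[scatter$concordant]))
  attr(out, "n_unlinked") <- sum(!have)
  out
}

#' Per-gene log fold change between two expression matrices
#'
#' Group-mean log-expression difference, `g1 - g2` so that with
#' `g1 = first`, `g2 = third` a positive value means higher expression
#' in first trimester (the convention used by [delta_vs_logfc()]).
#'
#' @param expr1,expr2 Gene x sample log-expression matrices.
#' @return Named numeric vector over the shared genes.
#' @export
expression_logfc <- function(expr1, expr2) {
  genes <- intersect(rownames(expr1), rownames(expr2))
  if (!length(genes)) stop("no shared genes between expression matrices")
  rowMeans(expr1[genes, , drop = FALSE]) -
    rowMeans(expr2[genes, , drop = FALSE])
}
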