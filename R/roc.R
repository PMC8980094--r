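#' ROC curve and AUC for a ranked gene list against a benchmark set
#'
#' Genes in `positives` are positive instances, the rest negative. The AUC
#' is computed by trapezoidal integration over the unique score thresholds,
#' which with the rank-sum tie convention (tied positive-negative pairs
#' count 1/2) equals the Mann-Whitney U divided by
#' `n_pos * n_neg`.
#'
#' @param ranked A [ranked_gene_list()].
#' @param positives Character vector of positive genes (must intersect the
#'   list, and not cover it).
#' @return List with `auc` and `roc` (data.frame of FPR/TPR points).
#' @export
roc_auc <- function(ranked, positives) {
  stopifnot(inherits(ranked, "ranked_genes"))
  lab <- ranked$gene %in% positives
  n_pos <- sum(lab); n_neg <- sum(!lab)
  if (n_pos == 0 || n_neg == 0)
    stop("positives must intersect the ranked genes without covering them")
  # Mann-Whitney with average ranks (ascending score: higher = predicted
  # positive)
  r <- rank(ranked$score, ties.method = "average")
  u <- sum(r[lab]) - n_pos * (n_pos + 1) / 2
  auc <- u / (n_pos * n_neg)
  # ROC points at unique descending thresholds
  ord <- order(ranked$score, decreasing = TRUE)
  sc <- ranked$score[ord]; lb <- lab[ord]
  cum_tp <- cumsum(lb); cum_fp <- cumsum(!lb)
  last <- !duplicated(sc, fromLast = TRUE)  # last index of each threshold
  roc <- data.frame(fpr = c(0, cum_fp[last] / n_neg),
                    tpr = c(0, cum_tp[last] / n_pos))
  list(auc = auc, roc = roc)
}

#' One-sided rank-shift test of a gene set in a ranked list
#'
#' Mann-Whitney-Wilcoxon test that the set genes have higher association
#' scores than the remaining genes (one-sided). The exact null is used for
#' small untied samples, and the normal approximation with tie correction
#' otherwise (via [stats::wilcox.test()]); the U statistic is also computed
#' directly.
#'
#' @param ranked A [ranked_gene_list()].
#' @param set Character vector of gene symbols.
#' @return List with `u` (Mann-Whitney U of set vs complement) and `p`
#'   (one-sided).
#' @export
rank_shift_test <- function(ranked, set) {
  stopifnot(inherits(ranked, "ranked_genes"))
  inset <- ranked$gene %in% set
  if (!any(inset) || all(inset)) stop("degenerate gene set")
  r <- rank(ranked$score, ties.method = "average")
  n1 <- sum(inset)
  u <- sum(r[inset]) - n1 * (n1 + 1) / 2
  wt <- suppressWarnings(stats::wilcox.test(
    ranked$score[inset], ranked$score[!inset], alternative = "greater"))
  list(u = unname(u), p = wt$p.value)
}

#' Prioritize druggable targets from the top of a ranked prediction
#'
#' Retains genes in the top `top_percentile` percent of the ranked
#' association list (inclusive at the boundary) that map to at least one
#' drug and are significantly upregulated (p < `p_cut`, linear fold change
#' > `fc_cut`). Output is sorted by percentile rank, most associated first,
#' with one row per gene and its drugs collapsed.
#'
#' @param ranked A [ranked_gene_list()].
#' @param drug_map Data.frame with `drug`, `gene` (one row per interaction).
#' @param de_table Data.frame with `gene`, `log2fc`, `p`.
#' @param top_percentile Percentile cut (default 15, inclusive).
#' @param p_cut Strict p-value cut (default 0.05).
#' @param fc_cut Strict linear fold-change cut (default 1.5).
#' @return Data.frame: compound, gene, log2fc, percentile_rank.
#' @export
prioritize_drug_targets <- function(ranked, drug_map, de_table,
                                    top_percentile = 15, p_cut = 0.05,
                                    fc_cut = 1.5) {
  stopifnot(inherits(ranked, "ranked_genes"))
  if (nrow(drug_map) == 0) stop("empty drug map")
  if (anyDuplicated(de_table$gene)) stop("duplicate genes in de_table")
  top <- ranked[ranked$percentile_rank <= top_percentile, , drop = FALSE]
  de <- de_table[match(top$gene, de_table$gene), , drop = FALSE]
  up <- !is.na(de$p) & de$p < p_cut & de$log2fc > log2(fc_cut)
  drugged <- top$gene %in% drug_map$gene
  keep <- top[up & drugged, , drop = FALSE]
  de <- de[up & drugged, , drop = FALSE]
  if (nrow(keep) == 0)
    return(data.frame(compound = character(0), gene = character(0),
                      log2fc = numeric(0), percentile_rank = numeric(0)))
  compounds <- vapply(keep$gene, function(g)
    paste(sort(unique(drug_map$drug[drug_map$gene == g])), collapse = ";"),
    "")
  out <- data.frame(compound = compounds, gene = keep$gene,
                    log2fc = de$log2fc,
                    percentile_rank = keep$percentile_rank,
                    stringsAsFactors = FALSE)
  out <- out[order(out$percentile_rank, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
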