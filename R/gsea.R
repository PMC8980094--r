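#' Ranked gene list with percentile ranks
#'
#' Orders genes by decreasing association score. The percentile rank lies in
#' \[0, 100\] with 0 the most associated gene; ties receive the average rank.
#'
#' @param gene Character vector of unique gene symbols.
#' @param score Numeric association scores (higher = more associated).
#' @return Object of class `ranked_genes`: data.frame with gene, score,
#'   rank (average rank, descending score) and percentile_rank.
#' @export
ranked_gene_list <- function(gene, score) {
  if (anyDuplicated(gene)) stop("genes must be unique")
  stopifnot(length(gene) == length(score), !anyNA(score))
  rk <- rank(-score, ties.method = "average")
  n <- length(gene)
  pct <- if (n > 1) 100 * (rk - 1) / (n - 1) else 0
  out <- data.frame(gene = as.character(gene), score = score, rank = rk,
                    percentile_rank = pct, stringsAsFactors = FALSE)
  out <- out[order(out$rank, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ranked_genes", "data.frame")
  out
}

# Signed maximum-deviation enrichment score from set positions in a ranked
# list. w: per-position weights (|score|^exponent); pos: sorted set positions.
.es_from_positions <- function(w, pos, n) {
  m <- length(pos)
  wsum <- sum(w[pos])
  hit_cum <- if (wsum > 0) cumsum(w[pos]) / wsum else
    cumsum(rep(1 / m, m))
  miss_unit <- 1 / (n - m)
  at_hit <- hit_cum - (pos - seq_len(m)) * miss_unit
  before_hit <- c(0, hit_cum[-m]) - (pos - seq_len(m)) * miss_unit
  cand <- c(at_hit, before_hit, 0)
  cand[which.max(abs(cand))]
}

#' GSEA enrichment score and permutation p-value
#'
#' Weighted Kolmogorov-Smirnov running-sum enrichment of a gene set in a
#' ranked list: hits accumulate `|score|^weight_exponent` (normalized over
#' the set), misses accumulate uniformly, and the enrichment score (ES) is
#' the signed maximum deviation of the running sum. Significance is assessed
#' by gene-label permutation (random sets of the same size), two-sided on
#' |ES|, with a +1 pseudocount in numerator and denominator.
#'
#' @param ranked A [ranked_gene_list()].
#' @param set Character vector of gene symbols.
#' @param n_perm Number of permutations (>= 100).
#' @param weight_exponent Weight on |score| (default 1; 0 gives the classic
#'   unweighted KS statistic).
#' @return List with `es`, `p`, `n_set` (genes in the intersection).
#' @export
gsea_enrichment <- function(ranked, set, n_perm = 1000L,
                            weight_exponent = 1) {
  stopifnot(inherits(ranked, "ranked_genes"), n_perm >= 100L)
  n <- nrow(ranked)
  pos <- sort(which(ranked$gene %in% set))
  m <- length(pos)
  if (m == 0) stop("gene set does not intersect the ranked list")
  if (m == n) stop("gene set covers the whole ranked list")
  w <- abs(ranked$score)^weight_exponent
  es <- .es_from_positions(w, pos, n)
  es_perm <- vapply(seq_len(n_perm), function(i)
    .es_from_positions(w, sort(sample.int(n, m)), n), 0)
  p <- (1 + sum(abs(es_perm) >= abs(es))) / (1 + n_perm)
  list(es = es, p = p, n_set = m)
}

#' Single-sample GSEA signature scores
#'
#' Per sample, genes are ranked by expression (rank 1 = lowest). The score
#' of a signature is the summed difference between the weighted in-set
#' empirical CDF (rank values raised to `alpha`) and the uniform out-of-set
#' CDF, walking the genes from highest to lowest expression. Scores depend
#' on the expression values only through their ranks, so any strictly
#' monotone transform of a sample leaves them unchanged.
#'
#' @param expr Samples x genes numeric matrix (named dimensions).
#' @param signatures Named list of gene sets.
#' @param alpha Rank-weight exponent (default 0.25).
#' @param normalize Min-max normalize each signature's scores across samples.
#' @return Samples x signatures score matrix (`NA` for signatures with no
#'   expressed genes, with a warning).
#' @export
ssgsea_scores <- function(expr, signatures, alpha = 0.25,
                          normalize = FALSE) {
  stopifnot(is.matrix(expr), !is.null(colnames(expr)),
            !is.null(names(signatures)))
  n <- ncol(expr)
  out <- matrix(NA_real_, nrow(expr), length(signatures),
                dimnames = list(rownames(expr), names(signatures)))
  for (s in seq_len(nrow(expr))) {
    r <- rank(expr[s, ], ties.method = "average")
    ord <- order(r, decreasing = TRUE)  # highest expression first
    genes_ord <- colnames(expr)[ord]
    w_ord <- r[ord]^alpha
    for (k in seq_along(signatures)) {
      inset <- genes_ord %in% signatures[[k]]
      m <- sum(inset)
      if (m == 0 || m == n) next
      p_in <- cumsum(ifelse(inset, w_ord, 0)) / sum(w_ord[inset])
      p_out <- cumsum(!inset) / (n - m)
      out[s, k] <- sum(p_in - p_out)
    }
  }
  empty <- colSums(!is.na(out)) == 0
  if (any(empty))
    warning("signature(s) with no expressed genes: ",
            paste(names(signatures)[empty], collapse = ", "))
  if (normalize) {
    rng <- apply(out, 2, function(x) diff(range(x, na.rm = TRUE)))
    mins <- apply(out, 2, min, na.rm = TRUE)
    out <- sweep(sweep(out, 2, mins), 2, ifelse(rng > 0, rng, 1), "/")
  }
  out
}
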