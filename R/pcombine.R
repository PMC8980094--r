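#' Truncated product combination of p-values
#'
#' Combines p-values by the product of those at or below the truncation
#' point tau, evaluated against its analytic null distribution under
#' independent Uniform(0, 1) p-values (Zaykin's closed-form sum):
#' \deqn{P(W^* \le w) = \sum_{k=1}^{L} \binom{L}{k} (1-\tau)^{L-k}
#'   \left[ 1(w \le \tau^k)\, w \sum_{s=0}^{k-1}
#'   \frac{(k \ln\tau - \ln w)^s}{s!} + 1(w > \tau^k)\, \tau^k \right]}
#' If no p-value falls at or below tau the product is empty (W = 1) and the
#' combined p is 1. With tau = 1 the method reduces to Fisher's method
#' (chi-square with 2L degrees of freedom).
#'
#' @param p_values Numeric p-values in (0, 1].
#' @param tau Truncation point in (0, 1] (default 0.05, the method's
#'   canonical choice).
#' @return Combined p-value in (0, 1].
#' @examples
#' truncated_product_combine(c(0.5, 0.5), tau = 0.05)  # empty product -> 1
#' truncated_product_combine(c(0.01, 0.5), tau = 0.05)
#' @export
truncated_product_combine <- function(p_values, tau = 0.05) {
  p <- as.numeric(p_values)
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  if (tau <= 0 || tau > 1) stop("tau must lie in (0, 1]")
  L <- length(p)
  below <- p[p <= tau]
  if (length(below) == 0) return(1)
  lw <- sum(log(below))  # log W
  total <- 0
  for (k in seq_len(L)) {
    if (tau == 1 && k < L) next  # (1 - tau)^(L-k) vanishes
    lbin <- lchoose(L, k) + if (k == L) 0 else (L - k) * log1p(-tau)
    if (lw <= k * log(tau)) {
      # w * sum_{s=0}^{k-1} (k ln tau - ln w)^s / s!, in log space via
      # the Poisson cdf: sum = e^x * P(Pois(x) <= k-1) with x = k ln tau - lw
      x <- k * log(tau) - lw
      term <- exp(lbin + lw + x + stats::ppois(k - 1, x, log.p = TRUE))
    } else {
      term <- exp(lbin + k * log(tau))
    }
    total <- total + term
  }
  min(1, total)
}

#' Combine association and deregulation pathway p-values
#'
#' Joins per-pathway results of a GSEA association analysis (ranked fusion
#' association list vs gene sets) with a GSEA deregulation analysis
#' (expression change vs the same sets) and combines the two p-values per
#' pathway with [truncated_product_combine()].
#'
#' @param assoc Data.frame with `pathway`, `es`, `p` (association analysis).
#' @param dereg Data.frame with `pathway`, `es`, `p` (deregulation analysis).
#' @param tau Truncation point.
#' @return Data.frame: pathway, es_assoc, p_assoc, es_dereg, p_dereg,
#'   p_combined, sorted by p_combined.
#' @export
combine_pathway_results <- function(assoc, dereg, tau = 0.05) {
  stopifnot(all(c("pathway", "es", "p") %in% names(assoc)),
            all(c("pathway", "es", "p") %in% names(dereg)))
  m <- merge(assoc, dereg, by = "pathway", suffixes = c("_assoc", "_dereg"))
  if (nrow(m) == 0) stop("no shared pathways between the two analyses")
  m$p_combined <- vapply(seq_len(nrow(m)), function(i)
    truncated_product_combine(c(m$p_assoc[i], m$p_dereg[i]), tau), 0)
  names(m)[names(m) == "es_assoc"] <- "es_assoc"
  m <- m[order(m$p_combined, m$pathway), , drop = FALSE]
  rownames(m) <- NULL
  m
}
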