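#' hg19 autosomal chromosome-arm table
#'
#' Arm boundaries for the 22 autosomes at hg19 scale, built from chromosome
#' lengths and centromere midpoints. Acrocentric chromosomes (13, 14, 15, 21,
#' 22) contribute only their q arm, giving 39 usable arms. Coordinates are
#' 1-based inclusive.
#'
#' @return A data.frame with columns `chrom`, `arm` (e.g. "1p"), `start`,
#'   `end`, `length`.
#' @export
hg19_arms <- function() {
  len <- c(249250621, 243199373, 198022430, 191154276, 180915260, 171115067,
           159138663, 146364022, 141213431, 135534747, 135006516, 133851895,
           115169878, 107349540, 102531392, 90354753, 81195210, 78077248,
           59128983, 63025520, 48129895, 51304566)
  # centromere midpoints (Mb), UCSC hg19 gap track
  cen <- c(125.0, 93.3, 91.0, 50.4, 48.4, 61.0, 59.9, 45.6, 49.0, 40.2,
           53.7, 35.8, 17.9, 17.6, 19.0, 36.6, 24.0, 17.2, 26.5, 27.5,
           13.2, 14.7) * 1e6
  acrocentric <- c(13L, 14L, 15L, 21L, 22L)
  rows <- lapply(seq_len(22L), function(i) {
    q <- data.frame(chrom = as.character(i), arm = paste0(i, "q"),
                    start = as.integer(cen[i]) + 1L, end = as.integer(len[i]),
                    stringsAsFactors = FALSE)
    if (i %in% acrocentric) return(q)
    p <- data.frame(chrom = as.character(i), arm = paste0(i, "p"),
                    start = 1L, end = as.integer(cen[i]),
                    stringsAsFactors = FALSE)
    rbind(p, q)
  })
  out <- do.call(rbind, rows)
  out$length <- out$end - out$start + 1L
  rownames(out) <- NULL
  out
}

#' Toy gene annotation over the packaged arm template
#'
#' Places `n_genes` synthetic genes deterministically across the hg19 arms,
#' allocated proportionally to arm length and spaced evenly within each arm.
#' Gene identifiers are `G0001`, `G0002`, ... in genomic order. This is a
#' synthetic desk-scale annotation: it preserves arm-level structure, not real
#' gene positions.
#'
#' @param n_genes Total number of genes to place (default 2000).
#' @return A data.frame with columns `gene`, `chrom`, `arm`, `start`, `end`
#'   (1-based inclusive).
#' @export
toy_genes <- function(n_genes = 2000L) {
  stopifnot(n_genes >= length(hg19_arms()$arm))
  arms <- hg19_arms()
  arm_len <- as.numeric(arms$length)
  n_per <- pmax(1L, as.integer(n_genes * arm_len / sum(arm_len)))
  # distribute any remainder to the largest arms, deterministically
  rem <- n_genes - sum(n_per)
  if (rem > 0) {
    ord <- order(arms$length, decreasing = TRUE)
    n_per[ord[seq_len(rem)]] <- n_per[ord[seq_len(rem)]] + 1L
  } else if (rem < 0) {
    ord <- order(arms$length)
    k <- 0L
    for (i in ord) {
      if (k == -rem) break
      if (n_per[i] > 1L) { n_per[i] <- n_per[i] - 1L; k <- k + 1L }
    }
  }
  rows <- lapply(seq_len(nrow(arms)), function(i) {
    k <- n_per[i]
    pos <- as.integer(arms$start[i] +
                        floor((seq_len(k) - 0.5) / k * arms$length[i]))
    data.frame(chrom = arms$chrom[i], arm = arms$arm[i],
               start = pos, end = pos + 999L, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(as.integer(out$chrom), out$start), , drop = FALSE]
  out <- cbind(gene = sprintf("G%04d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
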