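#' Quality-control thresholds for somatic variant calls
#'
#' High-quality somatic variants are those with tumor depth >= 30, matched
#' normal depth >= 15, tumor VAF >= 0.05 and normal VAF <= 0.01 (all bounds
#' inclusive). Driver calls additionally require population minor allele
#' frequency strictly below 0.01 in both ESP6500 and 1000 Genomes, a
#' non-silent consequence, and membership in a cancer-gene list.
#'
#' @param min_t_depth Minimum tumor read depth (inclusive).
#' @param min_n_depth Minimum matched-normal read depth (inclusive).
#' @param min_t_vaf Minimum tumor variant allele fraction (inclusive).
#' @param max_n_vaf Maximum normal variant allele fraction (inclusive).
#' @param driver_max_maf Strict upper bound on population MAF for driver
#'   classification.
#' @param nonsilent_classes Consequence classes counted as non-silent.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_t_depth = 30,
                          min_n_depth = 15,
                          min_t_vaf = 0.05,
                          max_n_vaf = 0.01,
                          driver_max_maf = 0.01,
                          nonsilent_classes = c("nonsynonymous", "stopgain",
                                                "stoploss", "splicing")) {
  thr <- list(min_t_depth = min_t_depth, min_n_depth = min_n_depth,
              min_t_vaf = min_t_vaf, max_n_vaf = max_n_vaf,
              driver_max_maf = driver_max_maf,
              nonsilent_classes = nonsilent_classes)
  stopifnot(min_t_depth >= 0, min_n_depth >= 0, min_t_vaf >= 0,
            max_n_vaf >= 0, min_t_vaf > max_n_vaf)
  class(thr) <- "qc_thresholds"
  thr
}

.consequence_vocab <- c("nonsynonymous", "stopgain", "stoploss", "splicing",
                        "synonymous", "other")

check_variant_table <- function(variants) {
  need <- c("t_depth", "t_alt", "n_depth", "n_alt")
  missing_col <- setdiff(need, names(variants))
  if (length(missing_col))
    stop("variant table lacks columns: ", paste(missing_col, collapse = ", "))
  for (cl in need) {
    v <- variants[[cl]]
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      stop(sprintf("missing %s for record %s", cl, variant_key(variants)[bad]))
    }
    if (any(v < 0)) stop("negative read counts in column ", cl)
  }
  if (any(variants$t_alt > variants$t_depth) ||
      any(variants$n_alt > variants$n_depth))
    stop("alt count exceeds depth")
  invisible(variants)
}

variant_key <- function(variants) {
  paste(variants$chrom, variants$pos, variants$ref, variants$alt, sep = ":")
}

#' Tumor variant allele fraction
#'
#' @param variants Variant data.frame with `t_alt`, `t_depth`.
#' @return Numeric VAF; `NA` where tumor depth is zero.
#' @export
tumor_vaf <- function(variants) {
  ifelse(variants$t_depth > 0, variants$t_alt / variants$t_depth, NA_real_)
}

#' Filter somatic calls to high-quality variants
#'
#' Keeps exactly the records with tumor depth >= `min_t_depth`, normal depth
#' >= `min_n_depth`, tumor VAF >= `min_t_vaf` and normal VAF <= `max_n_vaf`
#' (all inclusive). Input order is preserved. A zero normal depth is treated
#' as normal VAF 0 (no normal evidence of the allele).
#'
#' @param variants Data.frame of variant calls (see [read_maf()] for schema).
#' @param thr [qc_thresholds()].
#' @return The subset of `variants` passing all four bounds.
#' @examples
#' v <- data.frame(chrom = "1", pos = 1, ref = "A", alt = "T",
#'                 t_depth = 30, t_alt = 2, n_depth = 15, n_alt = 0)
#' nrow(filter_high_quality(v))  # kept: VAF 2/30 >= 0.05 at the boundary
#' @export
filter_high_quality <- function(variants, thr = qc_thresholds()) {
  check_variant_table(variants)
  if (nrow(variants) == 0) return(variants)
  t_vaf <- variants$t_alt / variants$t_depth
  t_vaf[variants$t_depth == 0] <- 0
  n_vaf <- variants$n_alt / variants$n_depth
  n_vaf[variants$n_depth == 0] <- 0
  keep <- variants$t_depth >= thr$min_t_depth &
    variants$n_depth >= thr$min_n_depth &
    t_vaf >= thr$min_t_vaf &
    n_vaf <= thr$max_n_vaf
  variants[keep, , drop = FALSE]
}

#' Flag putative driver mutations
#'
#' A variant is a driver candidate iff its population MAFs are strictly below
#' `driver_max_maf` in both ESP6500 and 1000 Genomes (a missing MAF is
#' treated as 0, i.e. novel), its consequence is non-silent, and it falls in
#' a known cancer gene (`is_cancer_gene`).
#'
#' @param variants Variant data.frame with `consequence`, `maf_esp6500`,
#'   `maf_1000g` and `is_cancer_gene` columns.
#' @param thr [qc_thresholds()].
#' @return Logical vector, one flag per record.
#' @export
classify_driver <- function(variants, thr = qc_thresholds()) {
  cons <- as.character(variants$consequence)
  unknown <- setdiff(unique(cons), .consequence_vocab)
  if (length(unknown))
    stop("unknown consequence token(s): ", paste(unknown, collapse = ", "))
  maf1 <- variants$maf_esp6500
  maf2 <- variants$maf_1000g
  maf1[is.na(maf1)] <- 0
  maf2[is.na(maf2)] <- 0
  maf1 < thr$driver_max_maf & maf2 < thr$driver_max_maf &
    cons %in% thr$nonsilent_classes &
    as.logical(variants$is_cancer_gene)
}

#' Mutation rate per megabase
#'
#' @param nonsilent_count Number of non-silent mutations in a sample.
#' @param capture_size_mb Exome capture size in megabases (> 0). No default:
#'   the rate is only meaningful relative to the capture actually used.
#' @return Mutations per Mb.
#' @examples
#' mutation_rate_per_mb(36, 50)  # 0.72
#' @export
mutation_rate_per_mb <- function(nonsilent_count, capture_size_mb) {
  if (any(capture_size_mb <= 0)) stop("capture_size_mb must be > 0")
  if (any(nonsilent_count < 0)) stop("counts must be non-negative")
  nonsilent_count / capture_size_mb
}

#' Per-sample mutation rates and cohort median
#'
#' Counts non-silent high-quality mutations per sample and converts to a per
#' megabase rate.
#'
#' @param variants Cohort variant data.frame with a `sample` column.
#' @param capture_size_mb Capture size in Mb.
#' @param thr [qc_thresholds()]; `nonsilent_classes` selects counted calls.
#' @return List with `per_sample` (data.frame: sample, n_nonsilent, rate) and
#'   `median_rate`.
#' @export
cohort_mutation_rates <- function(variants, capture_size_mb,
                                  thr = qc_thresholds()) {
  stopifnot("sample" %in% names(variants))
  if (any(capture_size_mb <= 0)) stop("capture_size_mb must be > 0")
  keep <- variants[as.character(variants$consequence) %in%
                     thr$nonsilent_classes, , drop = FALSE]
  counts <- table(factor(keep$sample, levels = unique(variants$sample)))
  per_sample <- data.frame(sample = names(counts),
                           n_nonsilent = as.integer(counts),
                           stringsAsFactors = FALSE)
  per_sample$rate <- mutation_rate_per_mb(per_sample$n_nonsilent,
                                          capture_size_mb)
  list(per_sample = per_sample,
       median_rate = stats::median(per_sample$rate))
}
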