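#' Simulation configuration for a synthetic multi-site cohort
#'
#' Bundles every parameter of the clonal-evolution simulator: cohort size,
#' sites per patient, clone structure (fractions of trunk, branch and private
#' mutations), tumor purity, the two sequencing coverage tiers, the per-base
#' sequencing error rate, detection thresholds, arm-level SCNA event rates,
#' and the expression/copy-number coupling.
#'
#' The defaults are the packaged "deep-validation" scenario: 60% of mutations
#' truncal, whole-exome coverage at a mean of 228X and deep targeted
#' re-genotyping at a mean of 3700X, tumor purity 0.4 (so a clonal
#' heterozygous mutation has expected VAF 0.5 x 0.4 = 0.2), and subclone
#' cancer-cell fractions drawn uniformly on [0.3, 0.8].
#'
#' @param n_patients Number of patients in the cohort.
#' @param site_range Integer range (length 2) of sites per patient, within
#'   \[2, 5\]; the number of sites is drawn uniformly from this range.
#' @param n_mutations Somatic mutations per patient (the per-patient union).
#' @param clone_fractions Numeric length-3 vector of (trunk, branch, private)
#'   mutation proportions; must be non-negative and sum to 1.
#' @param purity Tumor purity in (0, 1].
#' @param depth_wes Mean whole-exome coverage (reads).
#' @param depth_deep Mean deep targeted coverage (reads).
#' @param sequencing_error Per-base sequencing error rate.
#' @param ccf_range Range of subclone cancer-cell fractions for branch and
#'   private clones (trunk clones have CCF 1).
#' @param thresholds [qc_thresholds()] used when genotyping at the WES tier.
#' @param scna_rates Named list of per-arm event probabilities:
#'   `shared_gain`, `shared_loss` (trunk events applied to every site) and
#'   `private` (single-site events, gain or loss with equal probability).
#' @param expression_cn_slope log2 fold-change units per encoded copy-number
#'   unit when simulating expression.
#' @param expression_noise_sd Standard deviation of expression noise (log2FC
#'   units).
#' @param seed Integer seed; identical config + seed gives byte-identical
#'   output.
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_patients = 2, n_mutations = 20, seed = 1)
#' cfg
#' @export
sim_config <- function(n_patients = 20L,
                       site_range = c(2L, 5L),
                       n_mutations = 80L,
                       clone_fractions = c(trunk = 0.60, branch = 0.25,
                                           private = 0.15),
                       purity = 0.4,
                       depth_wes = 228,
                       depth_deep = 3700,
                       sequencing_error = 1e-3,
                       ccf_range = c(0.3, 0.8),
                       thresholds = qc_thresholds(),
                       scna_rates = list(shared_gain = 0.20,
                                         shared_loss = 0.15,
                                         private = 0.10),
                       expression_cn_slope = 1.0,
                       expression_noise_sd = 0.5,
                       seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              site_range = as.integer(site_range),
              n_mutations = as.integer(n_mutations),
              clone_fractions = clone_fractions,
              purity = purity,
              depth_wes = depth_wes,
              depth_deep = depth_deep,
              sequencing_error = sequencing_error,
              ccf_range = ccf_range,
              thresholds = thresholds,
              scna_rates = scna_rates,
              expression_cn_slope = expression_cn_slope,
              expression_noise_sd = expression_noise_sd,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_patients < 0L)
    stop("n_patients must be non-negative")
  if (length(cfg$site_range) != 2L || cfg$site_range[1] > cfg$site_range[2] ||
      cfg$site_range[1] < 2L || cfg$site_range[2] > 5L)
    stop("site_range must lie within [2, 5]")
  cf <- cfg$clone_fractions
  if (length(cf) != 3L || any(cf < 0) || abs(sum(cf) - 1) > 1e-9)
    stop("clone_fractions must be 3 non-negative proportions summing to 1")
  if (cfg$n_mutations <= 0L)
    stop("n_mutations must be positive")
  if (cfg$purity <= 0 || cfg$purity > 1)
    stop("purity must be in (0, 1]")
  if (cfg$depth_wes <= 0 || cfg$depth_deep <= 0)
    stop("coverage depths must be strictly positive")
  if (cfg$sequencing_error < 0 || cfg$sequencing_error >= 1)
    stop("sequencing_error must be in [0, 1)")
  if (length(cfg$ccf_range) != 2L || cfg$ccf_range[1] > cfg$ccf_range[2] ||
      cfg$ccf_range[1] <= 0 || cfg$ccf_range[2] > 1)
    stop("ccf_range must be an increasing range within (0, 1]")
  rates <- unlist(cfg$scna_rates)
  if (any(rates < 0) || any(rates > 1))
    stop("scna_rates must be probabilities in [0, 1]")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic multi-site cohort configuration\n")
  cat(sprintf("  patients: %d, sites per patient in [%d, %d], %d mutations each\n",
              x$n_patients, x$site_range[1], x$site_range[2], x$n_mutations))
  cat(sprintf("  clone fractions (trunk/branch/private): %.2f/%.2f/%.2f\n",
              x$clone_fractions[1], x$clone_fractions[2], x$clone_fractions[3]))
  cat(sprintf("  purity %.2f, coverage %gX (WES) / %gX (deep), error %.2g\n",
              x$purity, x$depth_wes, x$depth_deep, x$sequencing_error))
  cat(sprintf("  SCNA rates per arm: shared gain %.2f, shared loss %.2f, private %.2f\n",
              x$scna_rates$shared_gain, x$scna_rates$shared_loss,
              x$scna_rates$private))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}
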