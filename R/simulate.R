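#' Simulate one multi-site patient
#'
#' Draws the number of tumor sites, assigns each somatic mutation to a trunk,
#' branch or private clone according to the configured clone fractions, and
#' generates read counts at the two coverage tiers. The expected VAF of a
#' mutation where present is `0.5 * purity * CCF`, with CCF 1 for the trunk
#' clone and CCF drawn uniformly from `ccf_range` for branch/private
#' subclones. Observed depth is Poisson around the tier mean; the alt count
#' is Binomial(depth, VAF) where the mutation is present and
#' Binomial(depth, sequencing_error) where it is absent.
#'
#' With two sites a branch clone is impossible (a branch must be in more than
#' one but fewer than all sites), so branch-assigned mutations collapse to
#' private there; the trunk proportion is unaffected.
#'
#' Randomness is taken from the current RNG state; seed it (or use
#' [simulate_cohort()], which seeds from the config) for reproducibility.
#'
#' @param config [sim_config()].
#' @param patient_id Patient identifier.
#' @param n_sites Optional explicit number of sites (1 to 5); by default
#'   drawn uniformly from `config$site_range`.
#' @return List with elements `patient_id`, `samples` (site sample ids),
#'   `truth` (data.frame: mutation_id, category, sites_present, ccf),
#'   `true_vaf` (mutations x sites matrix), `wes` (long data.frame of
#'   per-(mutation, site) WES read counts with annotations, MAF-like schema)
#'   and `deep` (long data.frame of deep-tier counts: mutation_id, sample,
#'   depth, alt).
#' @export
simulate_patient <- function(config, patient_id, n_sites = NULL) {
  validate_sim_config(config)
  pick <- function(x) x[sample.int(length(x), 1L)]  # safe for length-1 x
  if (is.null(n_sites))
    n_sites <- pick(seq(config$site_range[1], config$site_range[2]))
  stopifnot(n_sites >= 1L, n_sites <= 5L)
  samples <- paste0(patient_id, letters[seq_len(n_sites)])
  n_mut <- config$n_mutations

  genes <- toy_genes()
  gi <- sort(sample.int(nrow(genes), n_mut, replace = n_mut > nrow(genes)))
  pos <- as.integer(genes$start[gi]) + sample.int(1000L, n_mut,
                                                  replace = TRUE) - 1L
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_mut, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
  key <- paste(genes$chrom[gi], pos, ref, alt, sep = ":")
  while (anyDuplicated(key)) {  # same gene drawn twice at the same offset
    dup <- which(duplicated(key))
    pos[dup] <- as.integer(genes$start[gi[dup]]) +
      sample.int(1000L, length(dup), replace = TRUE) - 1L
    key <- paste(genes$chrom[gi], pos, ref, alt, sep = ":")
  }
  consequence <- sample(.consequence_vocab, n_mut, replace = TRUE,
                        prob = c(0.60, 0.05, 0.01, 0.04, 0.25, 0.05))
  is_cancer_gene <- stats::runif(n_mut) < 0.05
  maf_esp <- ifelse(stats::runif(n_mut) < 0.05, stats::runif(n_mut, 0, 0.05), 0)
  maf_1kg <- ifelse(stats::runif(n_mut) < 0.05, stats::runif(n_mut, 0, 0.05), 0)

  category <- sample(c("trunk", "branch", "private"), n_mut, replace = TRUE,
                     prob = config$clone_fractions)
  if (n_sites == 1L) category[] <- "trunk"
  if (n_sites == 2L) category[category == "branch"] <- "private"

  present <- matrix(FALSE, n_mut, n_sites, dimnames = list(key, samples))
  for (i in seq_len(n_mut)) {
    present[i, ] <- switch(category[i],
      trunk = rep(TRUE, n_sites),
      private = seq_len(n_sites) %in% sample.int(n_sites, 1L),
      branch = seq_len(n_sites) %in%
        sample.int(n_sites, pick(seq(2L, n_sites - 1L))))
  }
  ccf <- ifelse(category == "trunk", 1,
                stats::runif(n_mut, config$ccf_range[1], config$ccf_range[2]))
  true_vaf <- present * (0.5 * config$purity * ccf)

  sim_counts <- function(depth_mean) {
    depth <- matrix(stats::rpois(n_mut * n_sites, depth_mean), n_mut, n_sites)
    p <- ifelse(present, true_vaf, config$sequencing_error)
    alt_n <- matrix(stats::rbinom(n_mut * n_sites, as.vector(depth),
                                  as.vector(p)), n_mut, n_sites)
    list(depth = depth, alt = alt_n)
  }
  wes_cnt <- sim_counts(config$depth_wes)
  deep_cnt <- sim_counts(config$depth_deep)
  n_depth <- matrix(stats::rpois(n_mut * n_sites, config$depth_wes),
                    n_mut, n_sites)
  n_alt <- matrix(stats::rbinom(n_mut * n_sites, as.vector(n_depth),
                                config$sequencing_error), n_mut, n_sites)

  wes <- data.frame(
    patient = patient_id,
    sample = rep(samples, each = n_mut),
    chrom = rep(genes$chrom[gi], n_sites),
    pos = rep(pos, n_sites),
    ref = rep(ref, n_sites),
    alt = rep(alt, n_sites),
    t_depth = as.vector(wes_cnt$depth),
    t_alt = as.vector(wes_cnt$alt),
    n_depth = as.vector(n_depth),
    n_alt = as.vector(n_alt),
    consequence = rep(consequence, n_sites),
    gene = rep(genes$gene[gi], n_sites),
    maf_esp6500 = rep(maf_esp, n_sites),
    maf_1000g = rep(maf_1kg, n_sites),
    stringsAsFactors = FALSE)
  wes$is_cancer_gene <- rep(is_cancer_gene, n_sites)
  wes$mutation_id <- rep(key, n_sites)

  deep <- data.frame(
    patient = patient_id,
    mutation_id = rep(key, n_sites),
    sample = rep(samples, each = n_mut),
    depth = as.vector(deep_cnt$depth),
    alt = as.vector(deep_cnt$alt),
    stringsAsFactors = FALSE)

  truth <- data.frame(
    patient_id = patient_id,
    mutation_id = key,
    true_category = category,
    sites_present = apply(present, 1L, function(p)
      paste(samples[p], collapse = ",")),
    ccf = ccf,
    stringsAsFactors = FALSE)

  list(patient_id = patient_id, samples = samples, truth = truth,
       true_vaf = true_vaf, wes = wes, deep = deep)
}

#' Simulate arm-level SCNA profiles for one patient
#'
#' Each autosomal arm independently receives a shared (trunk) gain (tCN 3)
#' with probability `scna_rates$shared_gain`, otherwise a shared loss (tCN 1)
#' with probability `scna_rates$shared_loss`; arms left neutral may instead
#' receive a private single-site event (gain or loss with equal probability)
#' with probability `scna_rates$private`. Shared events are applied to every
#' site. Every profile tiles each arm exactly once; the log2 ratio is
#' `log2(tCN / 2)`, with tCN 0 floored at -3.
#'
#' @param config [sim_config()].
#' @param patient_id Patient identifier.
#' @param samples Character vector of site sample ids.
#' @return List with `profiles` (one SEG-style data.frame per sample:
#'   sample, chrom, start, end, num_mark, seg_mean, tcn) and `events`
#'   (data.frame: arm, scope shared/private, sample (NA for shared), tcn).
#' @export
simulate_scna_profiles <- function(config, patient_id, samples) {
  validate_sim_config(config)
  arms <- hg19_arms()
  n_arm <- nrow(arms)
  u <- stats::runif(n_arm)
  g <- config$scna_rates$shared_gain
  l <- config$scna_rates$shared_loss
  shared_tcn <- ifelse(u < g, 3L, ifelse(u < g + l, 1L, 2L))
  events <- data.frame(arm = character(0), scope = character(0),
                       sample = character(0), tcn = integer(0),
                       stringsAsFactors = FALSE)
  tcn <- matrix(2L, n_arm, length(samples),
                dimnames = list(arms$arm, samples))
  for (a in seq_len(n_arm)) {
    if (shared_tcn[a] != 2L) {
      tcn[a, ] <- shared_tcn[a]
      events <- rbind(events, data.frame(
        arm = arms$arm[a], scope = "shared", sample = NA_character_,
        tcn = shared_tcn[a], stringsAsFactors = FALSE))
    } else if (stats::runif(1) < config$scna_rates$private) {
      s <- sample(seq_along(samples), 1L)
      t <- sample(c(1L, 3L), 1L)
      tcn[a, s] <- t
      events <- rbind(events, data.frame(
        arm = arms$arm[a], scope = "private", sample = samples[s],
        tcn = t, stringsAsFactors = FALSE))
    }
  }
  profiles <- lapply(seq_along(samples), function(s) {
    df <- data.frame(sample = samples[s], chrom = arms$chrom,
                     start = arms$start, end = arms$end,
                     num_mark = pmax(10L, arms$length %/% 100000L),
                     seg_mean = unname(log2_from_tcn(tcn[, s])),
                     tcn = unname(tcn[, s]), stringsAsFactors = FALSE)
    rownames(df) <- NULL
    df
  })
  names(profiles) <- samples
  list(profiles = profiles, events = events)
}

#' log2 ratio from integer total copy number
#'
#' `log2(tCN / 2)` with tCN 0 mapped to a finite floor.
#'
#' @param tcn Integer total copy numbers (>= 0).
#' @param zero_floor Value used for tCN 0 (default -3).
#' @export
log2_from_tcn <- function(tcn, zero_floor = -3) {
  ifelse(tcn == 0, zero_floor, log2(tcn / 2))
}

#' Simulate a differential-expression table coupled to copy number
#'
#' Each toy gene's log2 fold change is `expression_cn_slope` times the mean
#' encoded copy-number status of its arm across patients (shared events count
#' fully, private events by 1/n_sites), plus Gaussian noise. The p-value is a
#' deterministic monotone map of the fold change,
#' `p = 2 * pnorm(-|log2FC| / s)` with `s = expression_noise_sd` (or 1 when
#' the noise is 0), so larger fold changes always get smaller p.
#'
#' @param config [sim_config()].
#' @param scna_truth List of per-patient outputs of
#'   [simulate_scna_profiles()].
#' @return Data.frame with `gene`, `log2fc`, `p`.
#' @export
simulate_expression_table <- function(config, scna_truth) {
  validate_sim_config(config)
  genes <- toy_genes()
  arm_status <- stats::setNames(numeric(nrow(hg19_arms())), hg19_arms()$arm)
  n_pat <- length(scna_truth)
  if (n_pat > 0) {
    for (st in scna_truth) {
      ev <- st$events
      n_sites <- length(st$profiles)
      if (nrow(ev) == 0) next
      w <- ifelse(ev$scope == "shared", 1, 1 / n_sites)
      enc <- encode_tcn(ev$tcn)
      for (j in seq_len(nrow(ev)))
        arm_status[ev$arm[j]] <- arm_status[ev$arm[j]] + w[j] * enc[j]
    }
    arm_status <- arm_status / n_pat
  }
  mu <- config$expression_cn_slope * arm_status[genes$arm]
  log2fc <- mu + stats::rnorm(nrow(genes), 0, config$expression_noise_sd)
  s <- if (config$expression_noise_sd > 0) config$expression_noise_sd else 1
  p <- 2 * stats::pnorm(-abs(log2fc) / s)
  data.frame(gene = genes$gene, log2fc = as.numeric(log2fc),
             p = as.numeric(p), stringsAsFactors = FALSE)
}

#' Simulate a full multi-site cohort
#'
#' Seeds the RNG from the config and simulates every patient's mutations,
#' read counts at both tiers, SCNA profiles and the cohort expression table.
#' Identical config + seed gives identical output.
#'
#' @param config [sim_config()].
#' @param sites Optional integer vector of per-patient site counts
#'   (length `n_patients`); allows single-site patients, as in cohorts where
#'   only some patients have multi-site sampling. Default: drawn from
#'   `config$site_range`.
#' @return List of class `sim_cohort` with `config`, `patients` (list of
#'   [simulate_patient()] outputs), `scna` (list of
#'   [simulate_scna_profiles()] outputs) and `expression`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_patients = 2, n_mutations = 10,
#'                                      seed = 7))
#' names(cohort$patients)
#' @export
simulate_cohort <- function(config, sites = NULL) {
  validate_sim_config(config)
  if (!is.null(sites) && length(sites) != config$n_patients)
    stop("sites must have one entry per patient")
  set.seed(config$seed)
  ids <- sprintf("P%02d", seq_len(config$n_patients))
  patients <- list()
  scna <- list()
  for (i in seq_along(ids)) {
    ns <- if (is.null(sites)) NULL else sites[i]
    p <- simulate_patient(config, ids[i], n_sites = ns)
    patients[[ids[i]]] <- p
    scna[[ids[i]]] <- simulate_scna_profiles(config, ids[i], p$samples)
  }
  expression <- simulate_expression_table(config, scna)
  structure(list(config = config, patients = patients, scna = scna,
                 expression = expression),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  ns <- vapply(x$patients, function(p) length(p$samples), 0L)
  cat(sprintf("Synthetic cohort: %d patients (%d samples), seed %d\n",
              length(x$patients), sum(ns), x$config$seed))
  cat(sprintf("  sites per patient: %s\n", paste(ns, collapse = " ")))
  invisible(x)
}
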