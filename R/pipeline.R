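#' Pipeline configuration
#'
#' Reads a YAML configuration (or takes an equivalent list) and validates it
#' against the known schema; unknown keys are rejected. Sections: `seed`,
#' `simulation` (arguments of [sim_config()]), `thresholds`
#' ([qc_thresholds()] arguments), `rescue` ([rescue_rule()] arguments),
#' `scna` (`cutoff`, `min_patients`, `p_cut`, `fc_cut`), `enrichment`
#' (`n_perm`, `weight_exponent`, `tau`, `top_percentile`, `alpha`).
#'
#' @param config Path to a YAML file, or a named list.
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  known <- c("seed", "simulation", "thresholds", "rescue", "scna",
             "enrichment")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  sim_args <- config$simulation
  if (!is.null(sim_args)) {
    bad <- setdiff(names(sim_args), names(formals(sim_config)))
    if (length(bad))
      stop("unknown simulation keys: ", paste(bad, collapse = ", "))
  }
  thr <- do.call(qc_thresholds, config$thresholds %||% list())
  rule <- do.call(rescue_rule, config$rescue %||% list())
  scna <- utils::modifyList(list(cutoff = 0.25, min_patients = 4L,
                                 p_cut = 0.05, fc_cut = 1.5),
                            config$scna %||% list())
  enr <- utils::modifyList(list(n_perm = 1000L, weight_exponent = 1,
                                tau = 0.05, top_percentile = 15,
                                alpha = 0.25),
                           config$enrichment %||% list())
  sim <- do.call(sim_config, utils::modifyList(
    sim_args %||% list(), list(thresholds = thr, seed = seed)))
  structure(list(seed = seed, simulation = sim, thresholds = thr,
                 rescue = rule, scna = scna, enrichment = enr),
            class = "pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_manifest <- function(dir, stage, params, paths) {
  manifest <- list(stage = stage, params = params,
                   files = lapply(stats::setNames(paths, basename(paths)),
                                  function(f) unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Simulate a cohort and write its fixture files
#'
#' @param config A [pipeline_config()] (or argument thereto).
#' @param out_dir Output directory.
#' @param sites Optional per-patient site counts; `"paper_like"` gives a
#'   14-patient cohort where four patients carry 2, 2, 3 and 5 sites and the
#'   rest are single-site.
#' @param force Overwrite a non-empty directory.
#' @return Invisibly, the manifest list (seed, parameters, file checksums).
#' @export
run_simulate <- function(config = pipeline_config(), out_dir,
                         sites = NULL, force = FALSE) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !force)
    stop("output directory is not empty (use force = TRUE)")
  sim <- config$simulation
  if (identical(sites, "paper_like")) {
    sim$n_patients <- 14L
    sites <- c(2L, 2L, 3L, 5L, rep(1L, 10L))
  }
  cohort <- simulate_cohort(sim, sites = sites)
  paths <- write_fixtures(cohort, out_dir)
  manifest <- write_manifest(out_dir, "simulate",
                             list(seed = sim$seed,
                                  n_patients = sim$n_patients,
                                  n_mutations = sim$n_mutations),
                             paths)
  invisible(list(cohort = cohort, manifest = manifest))
}

#' Run the multi-site relatedness workflow
#'
#' For every multi-site patient: binary mutation matrix from the per-sample
#' detected calls, deep-coverage rescue, trunk/branch/private
#' classification, hamming distances, germline-rooted NJ trees (mutation and
#' SCNA), and intersample copy-number correlations. Single-site patients
#' are skipped with a warning.
#'
#' @param fixture_dir Directory written by [run_simulate()] (per-sample MAF
#'   and SEG files plus `deep_counts.tsv`), or equivalent real data.
#' @param out_dir Output directory for trees and summaries.
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with per-patient results and the cohort trunk
#'   fraction summary.
#' @export
run_relatedness <- function(fixture_dir, out_dir,
                            config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  maf_files <- sort(dir(fixture_dir, pattern = "\\.maf\\.tsv$",
                        full.names = TRUE))
  if (!length(maf_files)) stop("no MAF files in ", fixture_dir)
  calls <- do.call(rbind, lapply(maf_files, read_maf))
  deep <- read_deep_counts(file.path(fixture_dir, "deep_counts.tsv"))
  seg_files <- sort(dir(fixture_dir, pattern = "\\.seg\\.tsv$",
                        full.names = TRUE))
  segs <- do.call(rbind, lapply(seg_files, read_seg))
  patients <- unique(calls$patient)
  results <- list(); matrices <- list(); paths <- character(0)
  for (pid in patients) {
    pc <- calls[calls$patient == pid, , drop = FALSE]
    samples <- unique(pc$sample)
    if (length(samples) < 2L) {
      warning("patient ", pid, " has a single sample; phylogeny skipped")
      next
    }
    m <- build_binary_matrix(split(pc, pc$sample), patient_id = pid)
    m <- rescue_genotype(m, deep[deep$patient == pid, , drop = FALSE],
                         config$rescue)
    matrices[[pid]] <- m
    mt <- mutation_tree(m)
    pseg <- segs[segs$sample %in% samples, , drop = FALSE]
    sm_enc <- segments_to_site_matrix(pseg, scale = "encoded",
                                      patient_id = pid)
    sm_log <- segments_to_site_matrix(pseg, scale = "log2",
                                      patient_id = pid)
    st <- scna_tree(sm_enc)
    corr <- intersample_correlation(sm_log)
    f1 <- file.path(out_dir, paste0(pid, "_mutation_tree.nwk"))
    ape::write.tree(mt$tree, f1)
    f2 <- file.path(out_dir, paste0(pid, "_scna_tree.nwk"))
    ape::write.tree(st$tree, f2)
    f3 <- file.path(out_dir, paste0(pid, "_matrix.tsv"))
    utils::write.table(data.frame(mutation_id = rownames(m$mat), m$mat,
                                  category = m$category,
                                  check.names = FALSE),
                       f3, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, f1, f2, f3)
    results[[pid]] <- list(matrix = m, mutation_tree = mt, scna_tree = st,
                           correlation = corr,
                           mean_vaf = mean_vaf_by_category(pc, m))
  }
  if (!length(results)) stop("no multi-site patients found")
  summary <- trunk_fraction_summary(matrices)
  f <- file.path(out_dir, "trunk_summary.json")
  jsonlite::write_json(list(
    per_patient = summary$per_patient,
    mean_trunk_fraction = summary$mean_trunk_fraction,
    pooled_trunk_fraction = summary$pooled_trunk_fraction),
    f, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  paths <- c(paths, f)
  write_manifest(out_dir, "relatedness",
                 list(rescue = unclass(config$rescue)), paths)
  invisible(list(patients = results, summary = summary))
}

#' Run the enrichment / prioritization workflow
#'
#' Scores a ranked fusion-association gene list against gene sets (GSEA
#' association analysis), scores the expression deregulation of the same
#' sets (GSEA on the DE log2 fold changes), combines the two p-values per
#' pathway by the truncated product method, benchmarks the ranking by
#' ROC/AUC against positive gene sets, and prioritizes drug targets from
#' the top of the list.
#'
#' @param ranked A [ranked_gene_list()] (network association scores).
#' @param gene_sets Named list of pathways (e.g. [read_gmt()]).
#' @param de_table Data.frame with `gene`, `log2fc`, `p`.
#' @param drug_map Data.frame with `drug`, `gene`.
#' @param benchmark_sets Named list of positive gene sets for ROC/AUC.
#' @param out_dir Optional output directory for TSV/JSON reports.
#' @param config A [pipeline_config()].
#' @return List with `pathways` (combined table sorted by p_combined),
#'   `auc` (named numeric per benchmark set) and `targets`.
#' @export
run_enrichment <- function(ranked, gene_sets, de_table, drug_map,
                           benchmark_sets = list(), out_dir = NULL,
                           config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  enr <- config$enrichment
  if (!length(gene_sets)) stop("empty gene-set collection")
  if (!any(unlist(gene_sets) %in% ranked$gene))
    stop("gene sets share no symbols with the ranked list")
  dereg_ranked <- ranked_gene_list(de_table$gene, de_table$log2fc)
  assoc <- list(); dereg <- list()
  for (nm in names(gene_sets)) {
    a <- gsea_enrichment(ranked, gene_sets[[nm]], n_perm = enr$n_perm,
                         weight_exponent = enr$weight_exponent)
    d <- gsea_enrichment(dereg_ranked, gene_sets[[nm]],
                         n_perm = enr$n_perm,
                         weight_exponent = enr$weight_exponent)
    assoc[[nm]] <- data.frame(pathway = nm, es = a$es, p = a$p)
    dereg[[nm]] <- data.frame(pathway = nm, es = d$es, p = d$p)
  }
  pathways <- combine_pathway_results(do.call(rbind, assoc),
                                      do.call(rbind, dereg),
                                      tau = enr$tau)
  auc <- vapply(benchmark_sets, function(s) roc_auc(ranked, s)$auc, 0)
  targets <- prioritize_drug_targets(ranked, drug_map, de_table,
                                     top_percentile = enr$top_percentile,
                                     p_cut = config$scna$p_cut,
                                     fc_cut = config$scna$fc_cut)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- character(0)
    f <- file.path(out_dir, "pathways.tsv")
    utils::write.table(pathways, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, f)
    f <- file.path(out_dir, "drug_targets.tsv")
    utils::write.table(targets, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, f)
    f <- file.path(out_dir, "auc.json")
    jsonlite::write_json(as.list(auc), f, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, f)
    write_manifest(out_dir, "enrichment",
                   list(n_perm = enr$n_perm, tau = enr$tau,
                        top_percentile = enr$top_percentile), paths)
  }
  list(pathways = pathways, auc = auc, targets = targets)
}
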