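# File formats. All coordinates are 1-based inclusive.

#' Read / write MAF-like variant tables
#'
#' Tab-separated with columns: patient, sample, chrom, pos, ref, alt,
#' t_depth, t_alt, n_depth, n_alt, consequence, gene, maf_esp6500, maf_1000g
#' (and optionally is_cancer_gene, mutation_id).
#'
#' @param path File path.
#' @return `read_maf`: a data.frame in the schema above.
#' @export
read_maf <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(chrom = "character"))
  need <- c("patient", "sample", "chrom", "pos", "ref", "alt",
            "t_depth", "t_alt", "n_depth", "n_alt")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("MAF lacks columns: ", paste(miss, collapse = ", "))
  df
}

#' @rdname read_maf
#' @param variants Variant data.frame.
#' @export
write_maf <- function(variants, path) {
  utils::write.table(variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a minimal VCF v4.2 for one sample's somatic calls
#'
#' Emits one tumor genotype column with `GT:AD:DP` (AD = ref,alt depths).
#'
#' @param variants Variant data.frame (MAF-like schema) for one sample.
#' @param path Output path.
#' @param sample_id Sample column name; default taken from the table.
#' @export
write_vcf <- function(variants, path, sample_id = NULL) {
  if (is.null(sample_id))
    sample_id <- if (nrow(variants)) variants$sample[1] else "SAMPLE"
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=oncophylo",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_id, sep = "\t"))
  if (nrow(variants)) {
    ord <- order(as_chrom_num(variants$chrom), variants$pos)
    v <- variants[ord, , drop = FALSE]
    body <- paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS", ".",
                  "GT:AD:DP",
                  sprintf("0/1:%d,%d:%d", v$t_depth - v$t_alt, v$t_alt,
                          v$t_depth),
                  sep = "\t")
  } else body <- character(0)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read somatic calls from a VCF with AD/DP genotype fields
#'
#' Parses via \pkg{vcfR}. When tumor and normal columns are both present the
#' first is taken as tumor unless named; with a single genotype column the
#' normal counts are reported as `NA`.
#'
#' @param path VCF path.
#' @param tumor,normal Optional genotype column names.
#' @return Data.frame with chrom, pos, ref, alt, t_depth, t_alt and (when a
#'   normal column exists) n_depth, n_alt.
#' @export
read_vcf_variants <- function(path, tumor = NULL, normal = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt_samples <- colnames(v@gt)[-1]
  if (is.null(tumor)) tumor <- gt_samples[1]
  ad <- vcfR::extract.gt(v, "AD")
  dp <- vcfR::extract.gt(v, "DP", as.numeric = TRUE)
  split_ad <- function(x) {
    parts <- strsplit(x, ",", fixed = TRUE)
    vapply(parts, function(p) as.integer(p[2]), 0L)
  }
  out <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                    ref = fix$REF, alt = fix$ALT,
                    t_depth = as.integer(dp[, tumor]),
                    t_alt = split_ad(ad[, tumor]),
                    stringsAsFactors = FALSE)
  if (!is.null(normal) || length(gt_samples) > 1) {
    if (is.null(normal)) normal <- setdiff(gt_samples, tumor)[1]
    out$n_depth <- as.integer(dp[, normal])
    out$n_alt <- split_ad(ad[, normal])
  } else {
    out$n_depth <- NA_integer_
    out$n_alt <- NA_integer_
  }
  out
}

#' Read / write SEG copy-number segment files
#'
#' Tab-separated: sample, chrom, start, end, num_mark, seg_mean and
#' optionally tcn (integer total copy number). Coordinates 1-based
#' inclusive.
#'
#' @param path File path.
#' @return `read_seg`: a data.frame, one row per segment.
#' @export
read_seg <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(chrom = "character"))
  need <- c("sample", "chrom", "start", "end", "seg_mean")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("SEG lacks columns: ", paste(miss, collapse = ", "))
  df
}

#' @rdname read_seg
#' @param segments Segment data.frame.
#' @export
write_seg <- function(segments, path) {
  utils::write.table(segments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write GMT gene-set files
#'
#' `read_gmt` wraps `fgsea::gmtPathways`; `write_gmt` emits one line per set:
#' name, description, then member genes, tab-separated.
#'
#' @param path File path.
#' @return `read_gmt`: a named list of character vectors.
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  if (anyDuplicated(names(sets))) stop("duplicate gene-set names in GMT")
  if (any(lengths(sets) == 0)) stop("empty gene set in GMT")
  sets
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(length(names(sets)) == length(sets))
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a deep-targeted read-count table
#'
#' Tab-separated: patient, mutation_id (chrom:pos:ref:alt), sample, depth,
#' alt.
#'
#' @param path File path.
#' @export
read_deep_counts <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

as_chrom_num <- function(chrom) {
  x <- sub("^chr", "", as.character(chrom))
  n <- suppressWarnings(as.numeric(x))
  n[x == "X"] <- 23
  n[x == "Y"] <- 24
  n[is.na(n)] <- 25
  n
}

#' Write a simulated cohort to fixture files
#'
#' Per sample: a MAF-like TSV of WES calls passing the configured detection
#' thresholds, a minimal VCF v4.2 of the same calls, and a SEG file. Per
#' cohort: the clonal truth table, the deep-tier read counts, the
#' differential-expression table, and a GMT of planted arm gene sets (genes
#' on arms carrying shared gains/losses in the simulation). File order is
#' deterministic.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the vector of written paths.
#' @export
write_fixtures <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create output directory ", dir)
  paths <- character(0)
  thr <- cohort$config$thresholds
  truth_all <- list(); deep_all <- list()
  for (pid in names(cohort$patients)) {
    p <- cohort$patients[[pid]]
    truth_all[[pid]] <- p$truth
    deep_all[[pid]] <- p$deep
    for (s in p$samples) {
      calls <- p$wes[p$wes$sample == s, , drop = FALSE]
      detected <- filter_high_quality(calls, thr)
      f_maf <- file.path(dir, paste0(s, ".maf.tsv"))
      write_maf(detected, f_maf)
      f_vcf <- file.path(dir, paste0(s, ".vcf"))
      write_vcf(detected, f_vcf, sample_id = s)
      f_seg <- file.path(dir, paste0(s, ".seg.tsv"))
      write_seg(cohort$scna[[pid]]$profiles[[s]], f_seg)
      paths <- c(paths, f_maf, f_vcf, f_seg)
    }
  }
  truth_tab <- do.call(rbind, truth_all)
  if (is.null(truth_tab))
    truth_tab <- data.frame(patient_id = character(0),
                            mutation_id = character(0),
                            true_category = character(0),
                            sites_present = character(0), ccf = numeric(0))
  deep_tab <- do.call(rbind, deep_all)
  if (is.null(deep_tab))
    deep_tab <- data.frame(patient = character(0),
                           mutation_id = character(0),
                           sample = character(0), depth = integer(0),
                           alt = integer(0))
  f <- file.path(dir, "truth.tsv")
  utils::write.table(truth_tab, f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, f)
  f <- file.path(dir, "deep_counts.tsv")
  utils::write.table(deep_tab, f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, f)
  f <- file.path(dir, "expression_de.tsv")
  utils::write.table(cohort$expression, f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, f)
  genes <- toy_genes()
  shared_arms <- sort(unique(unlist(lapply(cohort$scna, function(s)
    s$events$arm[s$events$scope == "shared"]))))
  sets <- list()
  for (arm in shared_arms)
    sets[[paste0("planted_arm_", arm)]] <- genes$gene[genes$arm == arm]
  if (length(sets) == 0)
    sets$planted_none <- genes$gene[seq_len(min(10L, nrow(genes)))]
  f <- file.path(dir, "planted_sets.gmt")
  write_gmt(sets, f)
  paths <- c(paths, f)
  invisible(paths)
}
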