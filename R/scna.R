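#' Five-level encoding of integer total copy number
#'
#' Encodes segment copy-number status as: tCN 0 -> -2, 1 -> -1, 2 -> 0,
#' 3 -> 1, and >= 4 -> 2. Monotone non-decreasing in tCN.
#'
#' @param tcn Integer total copy number(s), >= 0.
#' @return Integer encoded status in \{-2, -1, 0, 1, 2\}.
#' @examples
#' encode_tcn(c(0, 1, 2, 3, 4, 7))  # -2 -1 0 1 2 2
#' @export
encode_tcn <- function(tcn) {
  if (any(is.na(tcn))) stop("tcn must not be missing")
  if (any(tcn < 0) || any(tcn != floor(tcn)))
    stop("tcn must be a non-negative integer")
  out <- pmin(as.integer(tcn), 4L) - 2L
  out
}

check_profile <- function(profile) {
  need <- c("sample", "chrom", "start", "end", "seg_mean")
  miss <- setdiff(need, names(profile))
  if (length(miss))
    stop("segment profile lacks columns: ", paste(miss, collapse = ", "))
  if (any(profile$start > profile$end)) stop("segment with start > end")
  for (chr in unique(profile$chrom)) {
    seg <- profile[profile$chrom == chr, , drop = FALSE]
    seg <- seg[order(seg$start), , drop = FALSE]
    if (nrow(seg) > 1 && any(seg$start[-1] <= seg$end[-nrow(seg)]))
      stop("overlapping segments within sample ", seg$sample[1],
           " on chromosome ", chr)
  }
  invisible(profile)
}

split_profiles <- function(profiles) {
  if (is.data.frame(profiles)) profiles <- split(profiles, profiles$sample)
  lapply(profiles, check_profile)
}

# Disjoint breakpoint-union intervals and per-sample covering values for one
# chromosome. value_col selects the emitted value.
chrom_union <- function(segs_by_sample, chr, value_col) {
  seg <- lapply(segs_by_sample, function(df)
    df[df$chrom == chr, , drop = FALSE])
  all <- do.call(rbind, seg)
  if (nrow(all) == 0) return(NULL)
  rng <- IRanges::IRanges(start = all$start, end = all$end)
  dj <- IRanges::disjoin(rng)
  # restrict to the union footprint (disjoin already covers exactly it)
  mat <- matrix(NA_real_, length(dj), length(seg),
                dimnames = list(NULL, names(seg)))
  for (s in seq_along(seg)) {
    if (nrow(seg[[s]]) == 0) next
    r <- IRanges::IRanges(start = seg[[s]]$start, end = seg[[s]]$end)
    ov <- IRanges::findOverlaps(dj, r)
    mat[S4Vectors::queryHits(ov), s] <-
      seg[[s]][[value_col]][S4Vectors::subjectHits(ov)]
  }
  list(intervals = data.frame(chrom = chr, start = IRanges::start(dj),
                              end = IRanges::end(dj),
                              stringsAsFactors = FALSE),
       values = mat)
}

#' Merge segment profiles of one patient's samples
#'
#' Aligns chromosome segments across the samples of a patient on the
#' breakpoint union: each output interval's log2 ratio is the unweighted
#' mean of the values of all samples covering it, while sample-specific
#' intervals keep that sample's value unchanged. The output tiles exactly
#' the union footprint of the input segments.
#'
#' @param profiles Named list of SEG-style data.frames (one per sample), or
#'   one data.frame with a `sample` column.
#' @param sample_id Sample id for the merged profile (default "merged").
#' @return A SEG-style data.frame (sample, chrom, start, end, num_mark =
#'   number of covering samples, seg_mean).
#' @export
merge_patient_segments <- function(profiles, sample_id = "merged") {
  segs <- split_profiles(profiles)
  chroms <- unique(unlist(lapply(segs, function(df) df$chrom)))
  chroms <- chroms[order(as_chrom_num(chroms))]
  out <- lapply(chroms, function(chr) {
    cu <- chrom_union(segs, chr, "seg_mean")
    if (is.null(cu)) return(NULL)
    data.frame(sample = sample_id, cu$intervals[, c("chrom", "start", "end")],
               num_mark = rowSums(!is.na(cu$values)),
               seg_mean = rowMeans(cu$values, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Site-by-sample SCNA matrix from segment profiles
#'
#' Rows are the disjoint breakpoint-union intervals over the patient's
#' samples; the entry for a sample is the value of its unique covering
#' segment (encoded status from tCN, or the log2 ratio), and `NA` where the
#' sample has no segment there.
#'
#' @param profiles Named list of SEG-style data.frames, or one data.frame
#'   with a `sample` column. The encoded scale requires a `tcn` column.
#' @param scale `"encoded"` (five-level status) or `"log2"`.
#' @param patient_id Optional patient identifier.
#' @return Object of class `scna_matrix`: list with `patient_id`,
#'   `intervals` (chrom, start, end), `mat` (intervals x samples), `scale`.
#' @export
segments_to_site_matrix <- function(profiles, scale = c("encoded", "log2"),
                                    patient_id = NULL) {
  scale <- match.arg(scale)
  segs <- split_profiles(profiles)
  if (length(segs) < 2L) stop("need at least 2 samples")
  if (scale == "encoded") {
    for (s in names(segs)) {
      if (!"tcn" %in% names(segs[[s]]))
        stop("encoded scale requires integer tcn in every profile")
      segs[[s]]$encoded <- encode_tcn(segs[[s]]$tcn)
    }
  }
  value_col <- if (scale == "encoded") "encoded" else "seg_mean"
  chroms <- unique(unlist(lapply(segs, function(df) df$chrom)))
  chroms <- chroms[order(as_chrom_num(chroms))]
  ints <- list(); vals <- list()
  for (chr in chroms) {
    cu <- chrom_union(segs, chr, value_col)
    if (is.null(cu)) next
    ints[[chr]] <- cu$intervals
    vals[[chr]] <- cu$values
  }
  structure(list(patient_id = patient_id,
                 intervals = do.call(rbind, ints),
                 mat = do.call(rbind, vals),
                 scale = scale),
            class = "scna_matrix")
}

#' SCNA phylogeny of one patient
#'
#' The germline ancestor has no SCNAs (all-zero encoded column). Distances
#' are hamming counts of intervals with differing encoded status (missing
#' coverage treated as diploid, encoded 0); the tree is neighbor joining
#' rooted at germline, with branch lengths proportional to the number of
#' shared and distinct SCNA segments.
#'
#' @param matrix An `scna_matrix` on the encoded scale.
#' @return A `tumor_phylo`-style list with `tree` and `dist`.
#' @export
scna_tree <- function(matrix) {
  stopifnot(inherits(matrix, "scna_matrix"))
  if (matrix$scale != "encoded")
    stop("SCNA trees require the encoded scale; encode tcn first")
  mat <- matrix$mat
  mat[is.na(mat)] <- 0
  d <- hamming_distance_matrix(mat)
  structure(list(patient_id = matrix$patient_id,
                 tree = phylo_tree(d), dist = d,
                 classification = NULL),
            class = "tumor_phylo")
}

#' Gene-level log2 copy-number from a merged profile
#'
#' Assigns each gene the log2 value of the segment containing its midpoint
#' (or, with `assign = "overlap"`, of the first overlapping segment).
#'
#' @param merged Merged SEG-style data.frame ([merge_patient_segments()]).
#' @param genes Gene annotation data.frame (gene, chrom, start, end).
#' @param assign `"midpoint"` (default) or `"overlap"`.
#' @return Named numeric vector of log2 values (`NA` where unassigned).
#' @export
gene_level_log2 <- function(merged, genes, assign = c("midpoint", "overlap")) {
  assign <- match.arg(assign)
  if (!all(c("gene", "chrom", "start", "end") %in% names(genes)))
    stop("missing gene annotation columns")
  out <- stats::setNames(rep(NA_real_, nrow(genes)), genes$gene)
  for (chr in unique(genes$chrom)) {
    seg <- merged[merged$chrom == chr, , drop = FALSE]
    g <- genes[genes$chrom == chr, , drop = FALSE]
    if (nrow(seg) == 0 || nrow(g) == 0) next
    if (assign == "midpoint") {
      mid <- floor((g$start + g$end) / 2)
      q <- IRanges::IRanges(start = mid, end = mid)
    } else {
      q <- IRanges::IRanges(start = g$start, end = g$end)
    }
    r <- IRanges::IRanges(start = seg$start, end = seg$end)
    ov <- IRanges::findOverlaps(q, r, select = "first")
    hit <- !is.na(ov)
    out[g$gene[hit]] <- seg$seg_mean[ov[hit]]
  }
  out
}

#' Per-patient gene-level log2 matrix for a cohort
#'
#' @param merged_by_patient Named list of merged profiles, one per patient.
#' @param genes Gene annotation data.frame.
#' @param assign Passed to [gene_level_log2()].
#' @return Genes x patients numeric matrix.
#' @export
cohort_gene_log2 <- function(merged_by_patient, genes,
                             assign = "midpoint") {
  mats <- vapply(merged_by_patient, gene_level_log2, numeric(nrow(genes)),
                 genes = genes, assign = assign)
  matrix(mats, nrow = nrow(genes),
         dimnames = list(genes$gene, names(merged_by_patient)))
}

#' Recurrent gene-level SCNAs across patients
#'
#' A gene is a recurrent gain iff its log2 score is >= `cutoff` in at least
#' `min_patients` patients, and a recurrent loss iff <= `-cutoff` in at
#' least `min_patients`. A gene crossing both thresholds in disjoint patient
#' sets appears in both lists and is flagged.
#'
#' @param gene_log2 Genes x patients log2 matrix ([cohort_gene_log2()]).
#' @param cutoff log2 score cutoff (default 0.25).
#' @param min_patients Minimum number of patients (default 4).
#' @return List with `gain`, `loss` (character vectors) and `both`.
#' @export
recurrent_scna_genes <- function(gene_log2, cutoff = 0.25,
                                 min_patients = 4L) {
  stopifnot(cutoff > 0, min_patients >= 1)
  n_gain <- rowSums(gene_log2 >= cutoff, na.rm = TRUE)
  n_loss <- rowSums(gene_log2 <= -cutoff, na.rm = TRUE)
  gain <- rownames(gene_log2)[n_gain >= min_patients]
  loss <- rownames(gene_log2)[n_loss >= min_patients]
  both <- intersect(gain, loss)
  if (length(both))
    warning(length(both), " gene(s) recurrent in both directions: ",
            paste(utils::head(both, 5), collapse = ", "))
  list(gain = gain, loss = loss, both = both)
}

#' Integrate recurrent SCNA genes with differential expression
#'
#' Retains recurrent-gain genes that are significantly upregulated
#' (p < `p_cut`, linear fold change > `fc_cut`) and recurrent-loss genes
#' significantly downregulated (fold change > `fc_cut` down); only
#' direction-concordant classes are emitted.
#'
#' @param recurrent [recurrent_scna_genes()] result.
#' @param de_table Data.frame with `gene`, `log2fc`, `p` (unique genes).
#' @param p_cut p-value cut (strict, default 0.05).
#' @param fc_cut Linear fold-change cut (strict, default 1.5).
#' @return Data.frame: gene, class (`up_gain` / `down_loss`), log2fc, p.
#' @export
integrate_with_expression <- function(recurrent, de_table, p_cut = 0.05,
                                      fc_cut = 1.5) {
  if (anyDuplicated(de_table$gene)) stop("duplicate genes in de_table")
  lfc_cut <- log2(fc_cut)
  de <- de_table
  up <- de[de$gene %in% recurrent$gain & de$p < p_cut &
             de$log2fc > lfc_cut, , drop = FALSE]
  dn <- de[de$gene %in% recurrent$loss & de$p < p_cut &
             de$log2fc < -lfc_cut, , drop = FALSE]
  out <- rbind(
    if (nrow(up)) data.frame(gene = up$gene, class = "up_gain",
                             log2fc = up$log2fc, p = up$p,
                             stringsAsFactors = FALSE),
    if (nrow(dn)) data.frame(gene = dn$gene, class = "down_loss",
                             log2fc = dn$log2fc, p = dn$p,
                             stringsAsFactors = FALSE))
  if (is.null(out))
    out <- data.frame(gene = character(0), class = character(0),
                      log2fc = numeric(0), p = numeric(0))
  rownames(out) <- NULL
  out
}

#' Pairwise Pearson correlation between samples' copy-number profiles
#'
#' Correlates the log2 values of the breakpoint-union intervals between
#' every pair of samples, with the p-value from the standard t transform.
#' A zero-variance sample yields `NA` correlations.
#'
#' @param matrix An `scna_matrix` on the log2 scale.
#' @return Data.frame: sample_a, sample_b, r, p.
#' @export
intersample_correlation <- function(matrix) {
  stopifnot(inherits(matrix, "scna_matrix"))
  if (matrix$scale != "log2")
    stop("intersample correlation expects the log2 scale")
  mat <- matrix$mat
  if (nrow(mat) < 3L) stop("need at least 3 intervals")
  samples <- colnames(mat)
  out <- list()
  for (i in seq_len(length(samples) - 1L))
    for (j in seq(i + 1L, length(samples))) {
      x <- mat[, i]; y <- mat[, j]
      ok <- stats::complete.cases(x, y)
      if (sum(ok) < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
        r <- NA_real_; p <- NA_real_
      } else {
        ct <- stats::cor.test(x[ok], y[ok])
        r <- unname(ct$estimate); p <- ct$p.value
      }
      out[[length(out) + 1L]] <- data.frame(
        sample_a = samples[i], sample_b = samples[j], r = r, p = p,
        stringsAsFactors = FALSE)
    }
  do.call(rbind, out)
}
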