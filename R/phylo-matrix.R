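#' Build a per-patient binary mutation presence/absence matrix
#'
#' Rows are the union of canonical variant keys (chrom:pos:ref:alt) detected
#' in at least one sample; entry 1 means the mutation was detected in that
#' sample. Rows are sorted genomically. Each entry carries a provenance
#' (`wes_detected` or `absent`; [rescue_genotype()] adds `deep_rescued`) and
#' each row a trunk/branch/private category: trunk = present in all samples,
#' private = in exactly one, branch = otherwise.
#'
#' @param per_sample_variants Named list (sample id -> variant data.frame
#'   with chrom, pos, ref, alt columns) of detected calls, or a single
#'   data.frame with a `sample` column.
#' @param patient_id Patient identifier (default from data).
#' @return An object of class `site_matrix`: list with `patient_id`, `mat`
#'   (0/1 integer matrix, mutations x samples), `provenance` (character
#'   matrix), `category` (character vector).
#' @examples
#' v <- function(keys) data.frame(
#'   chrom = sub(":.*", "", keys),
#'   pos = as.integer(sub("^[^:]+:([0-9]+):.*", "\\1", keys)),
#'   ref = "A", alt = "T")
#' m <- build_binary_matrix(list(s1 = v(c("1:100:A:T", "1:200:A:T")),
#'                               s2 = v("1:100:A:T")), "pat1")
#' m$category
#' @export
build_binary_matrix <- function(per_sample_variants, patient_id = NULL) {
  if (is.data.frame(per_sample_variants)) {
    stopifnot("sample" %in% names(per_sample_variants))
    per_sample_variants <- split(per_sample_variants,
                                 per_sample_variants$sample)
  }
  samples <- names(per_sample_variants)
  if (length(samples) < 2L) stop("need at least 2 samples for a site matrix")
  keys_by_sample <- lapply(per_sample_variants, function(df) {
    k <- variant_key(df)
    if (anyDuplicated(k)) stop("duplicate variant keys within a sample")
    k
  })
  all_keys <- unique(unlist(keys_by_sample))
  if (length(all_keys) == 0) stop("no detected mutations in any sample")
  chrom <- sub(":.*", "", all_keys)
  pos <- as.integer(vapply(strsplit(all_keys, ":", fixed = TRUE),
                           `[`, "", 2L))
  ord <- order(as_chrom_num(chrom), pos, all_keys)
  all_keys <- all_keys[ord]
  mat <- vapply(keys_by_sample, function(k)
    as.integer(all_keys %in% k), integer(length(all_keys)))
  mat <- matrix(mat, nrow = length(all_keys),
                dimnames = list(all_keys, samples))
  prov <- matrix(ifelse(mat == 1L, "wes_detected", "absent"),
                 nrow = nrow(mat), dimnames = dimnames(mat))
  if (is.null(patient_id)) {
    pid <- unique(unlist(lapply(per_sample_variants, function(df)
      df$patient)))
    patient_id <- if (length(pid) == 1) pid else NA_character_
  }
  out <- list(patient_id = patient_id, mat = mat, provenance = prov,
              category = row_category(mat))
  class(out) <- "site_matrix"
  out
}

row_category <- function(mat) {
  rs <- rowSums(mat != 0)
  if (any(rs == 0)) stop("all-zero mutation row violates the matrix invariant")
  ifelse(rs == ncol(mat), "trunk", ifelse(rs == 1L, "private", "branch"))
}

#' @export
print.site_matrix <- function(x, ...) {
  cat(sprintf("Site mutation matrix for %s: %d mutations x %d samples\n",
              x$patient_id, nrow(x$mat), ncol(x$mat)))
  tab <- table(factor(x$category, levels = c("trunk", "branch", "private")))
  cat(sprintf("  trunk %d, branch %d, private %d (trunk fraction %.3f)\n",
              tab["trunk"], tab["branch"], tab["private"],
              tab["trunk"] / nrow(x$mat)))
  rescued <- sum(x$provenance == "deep_rescued")
  if (rescued > 0) cat(sprintf("  %d cells rescued by deep re-genotyping\n",
                               rescued))
  invisible(x)
}

#' Deep-coverage rescue rule
#'
#' A 0-cell flips to present iff the deep alt count is at least `min_alt`
#' and the deep VAF at least `min_vaf`. The defaults (5 reads, VAF 0.01) are
#' permissive at ~3700X while excluding sequencing error at 0.1-0.5%.
#'
#' @param min_alt Minimum deep alternate read count.
#' @param min_vaf Minimum deep VAF.
#' @export
rescue_rule <- function(min_alt = 5, min_vaf = 0.01) {
  stopifnot(min_alt >= 0, min_vaf >= 0, min_vaf <= 1)
  structure(list(min_alt = min_alt, min_vaf = min_vaf),
            class = "rescue_rule")
}

#' Rescue low-VAF presences with deep targeted re-genotyping
#'
#' Re-genotypes every (mutation, sample) cell of the matrix at the deep
#' coverage tier: absent cells whose deep counts clear the rescue rule flip
#' to present with provenance `deep_rescued`. Present cells never flip back.
#' Categories are recomputed, so the trunk set can only grow.
#'
#' @param matrix A [build_binary_matrix()] result.
#' @param deep_counts Data.frame with `mutation_id`, `sample`, `depth`,
#'   `alt` covering every cell of the matrix; cells without deep coverage
#'   are warned about and left unchanged.
#' @param rule A [rescue_rule()].
#' @return The updated `site_matrix`.
#' @export
rescue_genotype <- function(matrix, deep_counts, rule = rescue_rule()) {
  stopifnot(inherits(matrix, "site_matrix"), inherits(rule, "rescue_rule"))
  mat <- matrix$mat
  prov <- matrix$provenance
  idx <- paste(deep_counts$mutation_id, deep_counts$sample, sep = "\r")
  depth <- stats::setNames(deep_counts$depth, idx)
  alt <- stats::setNames(deep_counts$alt, idx)
  missing_cells <- character(0)
  for (j in colnames(mat)) {
    cell <- paste(rownames(mat), j, sep = "\r")
    have <- cell %in% idx
    if (!all(have))
      missing_cells <- c(missing_cells, cell[!have])
    d <- depth[cell]
    a <- alt[cell]
    vaf <- ifelse(d > 0, a / d, 0)
    flip <- mat[, j] == 0L & have & a >= rule$min_alt & vaf >= rule$min_vaf
    mat[flip, j] <- 1L
    prov[flip, j] <- "deep_rescued"
  }
  if (length(missing_cells))
    warning(length(missing_cells),
            " matrix cell(s) lack deep coverage and were not re-genotyped")
  matrix$mat <- mat
  matrix$provenance <- prov
  matrix$category <- row_category(mat)
  matrix
}

#' Classify mutations as trunk, branch or private
#'
#' Trunk mutations are shared by all tissue sites, branch mutations by more
#' than one site, and private mutations are unique to a single site. The
#' trunk fraction is trunk rows over total rows.
#'
#' @param matrix A `site_matrix`.
#' @return List with `category`, `counts` (named trunk/branch/private) and
#'   `trunk_fraction`.
#' @export
classify_mutations <- function(matrix) {
  stopifnot(inherits(matrix, "site_matrix"))
  category <- row_category(matrix$mat)
  counts <- table(factor(category, levels = c("trunk", "branch", "private")))
  list(category = category,
       counts = stats::setNames(as.integer(counts), names(counts)),
       trunk_fraction = as.numeric(counts["trunk"]) / nrow(matrix$mat))
}

#' Cohort trunk-fraction summary
#'
#' Reports both the mean of per-patient trunk fractions (the headline
#' cross-patient average) and the pooled fraction over all mutations.
#'
#' @param matrices List of `site_matrix` objects.
#' @return List with `per_patient` (data.frame), `mean_trunk_fraction`,
#'   `pooled_trunk_fraction`.
#' @export
trunk_fraction_summary <- function(matrices) {
  per <- lapply(matrices, function(m) {
    cl <- classify_mutations(m)
    data.frame(patient_id = m$patient_id,
               n_mutations = nrow(m$mat),
               trunk = cl$counts["trunk"], branch = cl$counts["branch"],
               private = cl$counts["private"],
               trunk_fraction = cl$trunk_fraction,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  per <- do.call(rbind, per)
  list(per_patient = per,
       mean_trunk_fraction = mean(per$trunk_fraction),
       pooled_trunk_fraction = sum(per$trunk) / sum(per$n_mutations))
}

#' Mean tumor VAF by trunk/branch/private category
#'
#' Averages the tumor VAF over all (mutation, sample) cells where the
#' mutation is present, within each category. A category with no present
#' cells is reported as `NA`, not 0.
#'
#' @param variants Variant data.frame covering the matrix cells, with
#'   `sample`, `t_depth`, `t_alt` and `mutation_id` (or chrom/pos/ref/alt to
#'   derive it).
#' @param matrix A `site_matrix` with categories.
#' @return Named numeric: mean VAF for trunk, branch, private.
#' @export
mean_vaf_by_category <- function(variants, matrix) {
  stopifnot(inherits(matrix, "site_matrix"))
  if (!"mutation_id" %in% names(variants))
    variants$mutation_id <- variant_key(variants)
  vaf <- stats::setNames(tumor_vaf(variants),
                         paste(variants$mutation_id, variants$sample,
                               sep = "\r"))
  out <- c(trunk = NA_real_, branch = NA_real_, private = NA_real_)
  for (cat in names(out)) {
    rows <- which(matrix$category == cat)
    if (!length(rows)) next
    cells <- which(matrix$mat[rows, , drop = FALSE] == 1L, arr.ind = TRUE)
    keys <- paste(rownames(matrix$mat)[rows][cells[, 1]],
                  colnames(matrix$mat)[cells[, 2]], sep = "\r")
    v <- vaf[keys]
    v <- v[!is.na(v)]
    if (length(v)) out[cat] <- mean(v)
  }
  out
}
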