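# Shared fixtures, built in code.

# Variant table from canonical keys, with passing read counts by default.
variants_from_keys <- function(keys, sample = "s1", patient = "p1",
                               t_depth = 100, t_alt = 30, n_depth = 50,
                               n_alt = 0) {
  parts <- strsplit(keys, ":", fixed = TRUE)
  data.frame(patient = patient, sample = sample,
             chrom = vapply(parts, `[`, "", 1L),
             pos = as.integer(vapply(parts, `[`, "", 2L)),
             ref = vapply(parts, `[`, "", 3L),
             alt = vapply(parts, `[`, "", 4L),
             t_depth = as.integer(t_depth), t_alt = as.integer(t_alt),
             n_depth = as.integer(n_depth), n_alt = as.integer(n_alt),
             stringsAsFactors = FALSE)
}

# Site matrix directly from a 0/1 matrix (rows auto-keyed).
matrix_from_binary <- function(mat, patient_id = "p1") {
  keys <- sprintf("1:%d:A:T", seq_len(nrow(mat)) * 100L)
  per_sample <- lapply(seq_len(ncol(mat)), function(j)
    variants_from_keys(keys[mat[, j] == 1]))
  names(per_sample) <- colnames(mat)
  build_binary_matrix(per_sample, patient_id)
}

# Deep-count table covering every cell of a site matrix.
deep_counts_for <- function(m, depth = 3700, alt_present = 400,
                            alt_absent = 2) {
  cells <- expand.grid(mutation_id = rownames(m$mat),
                       sample = colnames(m$mat),
                       stringsAsFactors = FALSE)
  present <- m$mat[cbind(match(cells$mutation_id, rownames(m$mat)),
                         match(cells$sample, colnames(m$mat)))] == 1
  data.frame(patient = m$patient_id, cells, depth = depth,
             alt = ifelse(present, alt_present, alt_absent),
             stringsAsFactors = FALSE)
}

# Arm-level SEG profile helper: named vector arm -> tcn.
profile_from_arms <- function(sample_id, tcn_by_arm = c()) {
  arms <- hg19_arms()
  tcn <- rep(2L, nrow(arms))
  names(tcn) <- arms$arm
  tcn[names(tcn_by_arm)] <- tcn_by_arm
  df <- data.frame(sample = sample_id, chrom = arms$chrom,
                   start = arms$start, end = arms$end, num_mark = 100L,
                   seg_mean = unname(log2_from_tcn(tcn)),
                   tcn = unname(as.integer(tcn)), stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}

# Independent brute-force GSEA running sum (O(N) walk), used as oracle.
brute_force_es <- function(scores, inset, weight_exponent = 1) {
  ord <- order(scores, decreasing = TRUE)
  inset <- inset[ord]
  w <- abs(scores[ord])^weight_exponent
  n <- length(scores); m <- sum(inset)
  p_hit <- cumsum(ifelse(inset, w, 0)) / sum(w[inset])
  p_miss <- cumsum(!inset) / (n - m)
  dev <- p_hit - p_miss
  dev[which.max(abs(dev))]
}
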