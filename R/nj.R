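#' Hamming distance matrix over samples, with a germline ancestor
#'
#' The distance between two samples is the number of matrix rows (mutations
#' or encoded SCNA segments) where their values differ. An all-zero
#' `germline` column is appended before computation, so the distance from a
#' sample to germline is its number of non-zero entries.
#'
#' @param matrix A `site_matrix`, or a plain numeric matrix (rows = loci,
#'   columns = samples) of 0/1 or encoded values.
#' @param add_germline Append the all-zero germline column (default TRUE).
#' @return A symmetric matrix of counts with zero diagonal.
#' @examples
#' m <- rbind(c(1, 1), c(1, 0))
#' colnames(m) <- c("s1", "s2")
#' hamming_distance_matrix(m)
#' @export
hamming_distance_matrix <- function(matrix, add_germline = TRUE) {
  mat <- if (inherits(matrix, "site_matrix")) matrix$mat else as.matrix(matrix)
  if (is.null(colnames(mat)))
    colnames(mat) <- paste0("s", seq_len(ncol(mat)))
  if (ncol(mat) < 2L) stop("need at least 2 samples")
  if (add_germline) {
    if ("germline" %in% colnames(mat))
      stop("matrix already contains a germline column")
    mat <- cbind(mat, germline = 0)
  }
  n <- ncol(mat)
  d <- matrix(0, n, n, dimnames = list(colnames(mat), colnames(mat)))
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    d[i, j] <- d[j, i] <- sum(mat[, i] != mat[, j])
  }
  d
}

#' Neighbor-joining tree reconstruction
#'
#' Classical Saitou-Nei agglomeration: at each step the pair minimizing the
#' Q criterion `Q(i,j) = (r - 2) d(i,j) - R_i - R_j` is joined, with branch
#' lengths from the standard formulas. Ties in Q are broken by lexicographic
#' order of the joined taxon-label pair. Negative branch-length estimates
#' are clamped to 0. For two taxa the single edge is returned (split evenly
#' across the root).
#'
#' @param dist Symmetric distance matrix with zero diagonal and labelled
#'   rows/columns.
#' @return An unrooted `phylo` tree (package \pkg{ape}).
#' @examples
#' d <- matrix(c(0, 4, 6, 4, 0, 8, 6, 8, 0), 3,
#'             dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
#' tr <- neighbor_joining(d)  # branch lengths 1, 3, 5
#' @export
neighbor_joining <- function(dist) {
  d <- as.matrix(dist)
  if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-9))
    stop("distance matrix must be symmetric")
  if (any(d < 0)) stop("negative distances are not allowed")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix must have zero diagonal")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(nrow(d)))
  n <- length(labels)
  if (n < 2L) stop("need at least 2 taxa")
  rep_nwk <- labels  # newick fragment per active cluster
  act <- labels      # active cluster labels, used for tie-breaking
  if (n == 2L) {
    nwk <- sprintf("(%s:%.17g,%s:%.17g);", rep_nwk[1], d[1, 2] / 2,
                   rep_nwk[2], d[1, 2] / 2)
    return(clamp_lengths(ape::read.tree(text = nwk)))
  }
  while (length(act) > 3L) {
    r <- length(act)
    R <- rowSums(d)
    best <- NULL; best_q <- Inf
    for (i in seq_len(r - 1L)) for (j in seq(i + 1L, r)) {
      q <- (r - 2) * d[i, j] - R[i] - R[j]
      if (q < best_q - 1e-12) {
        best_q <- q; best <- c(i, j)
      } else if (abs(q - best_q) <= 1e-12) {
        cand <- sort(c(act[i], act[j])); cur <- sort(c(act[best[1]],
                                                       act[best[2]]))
        if (cand[1] < cur[1] || (cand[1] == cur[1] && cand[2] < cur[2]))
          best <- c(i, j)
      }
    }
    i <- best[1]; j <- best[2]
    li <- d[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    lj <- d[i, j] - li
    du <- (d[i, ] + d[j, ] - d[i, j]) / 2
    new_nwk <- sprintf("(%s:%.17g,%s:%.17g)", rep_nwk[i], li, rep_nwk[j], lj)
    new_lab <- paste0("(", min(act[i], act[j]), ")")
    keep <- setdiff(seq_len(r), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], du[keep]),
               c(du[keep], 0))
    rep_nwk <- c(rep_nwk[keep], new_nwk)
    act <- c(act[keep], new_lab)
    dimnames(d) <- list(act, act)
  }
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  nwk <- sprintf("(%s:%.17g,%s:%.17g,%s:%.17g);",
                 rep_nwk[1], la, rep_nwk[2], lb, rep_nwk[3], lc)
  clamp_lengths(ape::read.tree(text = nwk))
}

clamp_lengths <- function(tree) {
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Germline-rooted phylogeny from a distance matrix
#'
#' Runs [neighbor_joining()] and roots the tree at the germline leaf
#' (all-zero ancestor) for reporting.
#'
#' @param dist Distance matrix including a `germline` row/column (as
#'   produced by [hamming_distance_matrix()]).
#' @param root Leaf to root at (default `"germline"`).
#' @return A rooted `phylo` tree.
#' @export
phylo_tree <- function(dist, root = "germline") {
  tree <- neighbor_joining(dist)
  if (!root %in% tree$tip.label)
    stop("root leaf '", root, "' is not in the tree")
  if (length(tree$tip.label) > 2L)
    tree <- ape::root(tree, outgroup = root, resolve.root = TRUE)
  tree
}

#' Mutation phylogeny for one patient
#'
#' Convenience wrapper: hamming distances over the binary site matrix (with
#' the germline ancestor appended), neighbor joining, germline rooting.
#' Branch lengths are in alteration counts (real-valued after NJ
#' estimation); the raw mismatch-count distance matrix is returned alongside
#' since reported branch lengths may be read either way.
#'
#' @param matrix A `site_matrix`.
#' @return List of class `tumor_phylo` with `tree` (rooted `phylo`),
#'   `dist`, `classification` ([classify_mutations()]) and `patient_id`.
#' @export
mutation_tree <- function(matrix) {
  stopifnot(inherits(matrix, "site_matrix"))
  d <- hamming_distance_matrix(matrix)
  structure(list(patient_id = matrix$patient_id,
                 tree = phylo_tree(d),
                 dist = d,
                 classification = classify_mutations(matrix)),
            class = "tumor_phylo")
}

#' @export
print.tumor_phylo <- function(x, ...) {
  cl <- x$classification
  cat(sprintf("Multi-site tumor phylogeny for %s (%d samples + germline)\n",
              x$patient_id, length(x$tree$tip.label) - 1L))
  cat(sprintf("  trunk %d, branch %d, private %d (trunk fraction %.3f)\n",
              cl$counts["trunk"], cl$counts["branch"], cl$counts["private"],
              cl$trunk_fraction))
  cat("  newick: ", ape::write.tree(x$tree), "\n", sep = "")
  invisible(x)
}

#' @export
plot.tumor_phylo <- function(x, ...) {
  ape::plot.phylo(x$tree, ...)
  invisible(x)
}
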