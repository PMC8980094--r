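test_that("ranked lists assign percentile 0 to the top gene with average-rank ties", {
  r <- ranked_gene_list(c("a", "b", "c", "d", "e"), c(5, 4, 4, 2, 1))
  expect_identical(r$gene[1], "a")
  expect_equal(r$percentile_rank[1], 0)
  expect_equal(r$percentile_rank[r$gene == "e"], 100)
  expect_equal(r$rank[r$gene %in% c("b", "c")], c(2.5, 2.5))
  expect_error(ranked_gene_list(c("a", "a"), 1:2), "unique")
})

test_that("GSEA enrichment matches a pencil-and-paper running sum", {
  scores <- c(10, 9, 8, 7, 6, 5, 4, 3, 2, 1)
  genes <- paste0("g", 1:10)
  r <- ranked_gene_list(genes, scores)
  set <- c("g1", "g4", "g5")
  # manual weighted running sum: hits at positions 1, 4, 5
  wsum <- 10 + 7 + 6
  run <- c(10 / wsum,                      # g1 hit
           10 / wsum - 1 / 7,              # g2 miss
           10 / wsum - 2 / 7,              # g3 miss
           17 / wsum - 2 / 7,              # g4 hit
           23 / wsum - 2 / 7)              # g5 hit; later only misses
  es_manual <- run[which.max(abs(c(run, run[5] - 5 / 7)))]
  set.seed(71)
  out <- gsea_enrichment(r, set, n_perm = 200)
  expect_lt(abs(out$es - es_manual), 1e-12)
  expect_lt(abs(out$es - brute_force_es(scores, genes %in% set)), 1e-12)
})

test_that("a set occupying the top ranks attains the maximal ES and minimal p", {
  n <- 50
  r <- ranked_gene_list(paste0("g", 1:n), n:1)
  set <- paste0("g", 1:5)
  set.seed(72)
  out <- gsea_enrichment(r, set, n_perm = 500)
  # maximum attainable: full hit mass accumulated before any miss
  expect_equal(out$es, 1 - 0)
  expect_lte(out$p, 1 / 501 + 1e-12)
  expect_error(gsea_enrichment(r, "absent"), "intersect")
})

test_that("a set at the very top keeps ES 1 when trailing genes are appended", {
  scores <- c(9, 8, 7, 6, 5)
  genes <- paste0("g", 1:5)
  set <- c("g1", "g2")
  # full hit mass accumulates before any miss, so the maximal deviation is 1
  # in both weighting modes, regardless of genes appended below the set
  for (expo in c(0, 1)) {
    es <- brute_force_es(scores, genes %in% set, weight_exponent = expo)
    es_ext <- brute_force_es(c(scores, 1, 0.5),
                             c(genes, "x1", "x2") %in% set,
                             weight_exponent = expo)
    expect_equal(es, 1)
    expect_equal(es_ext, 1)
  }
})

test_that("ssGSEA scores match a hand-computed ECDF sum and are rank-invariant", {
  expr <- matrix(c(5, 4, 3, 2, 1), 1,
                 dimnames = list("s1", paste0("g", 1:5)))
  sig <- list(top2 = c("g1", "g2"))
  alpha <- 0.25
  # manual: ranks 5..1, order g1..g5, weights rank^alpha
  w <- (5:1)^alpha
  p_in <- cumsum(c(w[1], w[2], 0, 0, 0)) / (w[1] + w[2])
  p_out <- cumsum(c(0, 0, 1, 1, 1)) / 3
  manual <- sum(p_in - p_out)
  s <- ssgsea_scores(expr, sig, alpha = alpha)
  expect_equal(unname(s[1, 1]), manual)
  # strictly monotone transform leaves scores unchanged
  s2 <- ssgsea_scores(exp(expr), sig, alpha = alpha)
  expect_equal(s, s2)
  # the top-ranked signature attains the sample's maximum score
  sigs <- list(top2 = c("g1", "g2"), bottom2 = c("g4", "g5"))
  s3 <- ssgsea_scores(expr, sigs, alpha = alpha)
  expect_gt(s3[1, "top2"], s3[1, "bottom2"])
  expect_warning(ssgsea_scores(expr, list(none = "zz")), "no expressed")
})

test_that("truncated product reduces to known cases", {
  # empty product
  expect_identical(truncated_product_combine(c(0.5, 0.5), tau = 0.05), 1)
  # tau = 1 equals Fisher's method
  for (p in list(c(0.1, 0.2), c(0.01, 0.5, 0.9), c(0.3, 0.3, 0.3, 0.3))) {
    fisher <- pchisq(-2 * sum(log(p)), df = 2 * length(p),
                     lower.tail = FALSE)
    expect_lt(abs(truncated_product_combine(p, tau = 1) - fisher), 1e-10)
  }
  # single p below tau: P(W <= w) = tau * (w/tau stays) -- check against
  # direct integration for L = 1: P = w for w <= tau... plus mass above tau
  expect_equal(truncated_product_combine(0.01, tau = 0.05), 0.01)
  expect_error(truncated_product_combine(c(0, 0.5)), "0, 1")
})

test_that("truncated product is monotone in each input p-value", {
  set.seed(73)
  for (i in 1:50) {
    p <- runif(3)
    j <- sample(3, 1)
    p2 <- p
    p2[j] <- p[j] * runif(1)  # decrease one input
    expect_lte(truncated_product_combine(p2, 0.05),
               truncated_product_combine(p, 0.05) + 1e-12)
  }
})

test_that("ROC AUC equals the concordant-pair count and handles extremes", {
  genes <- paste0("g", 1:20)
  r <- ranked_gene_list(genes, 20:1)
  pos <- paste0("g", 1:6)
  expect_equal(roc_auc(r, pos)$auc, 1)
  r_inv <- ranked_gene_list(genes, 1:20)
  expect_equal(roc_auc(r_inv, pos)$auc, 0)
  # brute-force pair enumeration with ties
  set.seed(74)
  sc <- sample(1:8, 20, TRUE)
  rt <- ranked_gene_list(genes, sc)
  pos6 <- sample(genes, 6)
  res <- roc_auc(rt, pos6)
  s_pos <- sc[genes %in% pos6]; s_neg <- sc[!genes %in% pos6]
  conc <- 0
  for (a in s_pos) for (b in s_neg)
    conc <- conc + (a > b) + 0.5 * (a == b)
  expect_equal(res$auc, conc / (length(s_pos) * length(s_neg)))
  # curve endpoints
  expect_equal(unlist(res$roc[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unname(unlist(res$roc[nrow(res$roc), ])), c(1, 1))
  expect_error(roc_auc(rt, genes), "covering")
})

test_that("rank-shift U equals hand enumeration and ties AUC to the U statistic", {
  genes <- paste0("g", 1:8)
  r <- ranked_gene_list(genes, c(8, 7, 6, 5, 4, 3, 2, 1))
  set <- c("g1", "g2", "g5")
  out <- rank_shift_test(r, set)
  s_in <- c(8, 7, 4); s_out <- c(6, 5, 3, 2, 1)
  u_manual <- 0
  for (a in s_in) for (b in s_out)
    u_manual <- u_manual + (a > b) + 0.5 * (a == b)
  expect_equal(out$u, u_manual)
  # AUC-U identity on random inputs, exact
  set.seed(75)
  for (i in 1:10) {
    sc <- sample(1:10, 30, TRUE)
    rr <- ranked_gene_list(paste0("x", 1:30), sc)
    pos <- sample(rr$gene, 8)
    auc <- roc_auc(rr, pos)$auc
    u <- rank_shift_test(rr, pos)$u
    expect_equal(auc * (8 * 22), u)
  }
  # top-k set attains the minimal one-sided p for its configuration
  top <- rank_shift_test(r, c("g1", "g2", "g3"))
  expect_lt(top$p, rank_shift_test(r, c("g6", "g7", "g8"))$p)
  expect_error(rank_shift_test(r, character(0)), "degenerate")
})

test_that("drug-target prioritization reproduces the three-condition intersection", {
  set.seed(76)
  n <- 1000
  genes <- c("AR", paste0("g", 2:n))
  scores <- c(999, sort(runif(n - 1, 0, 900), decreasing = TRUE))
  r <- ranked_gene_list(genes, scores)
  # AR lands at the top with a tiny percentile rank
  de <- data.frame(gene = genes, log2fc = rnorm(n, 0, 1), p = runif(n))
  de$log2fc[1] <- 1.91; de$p[1] <- 1e-6
  dm <- data.frame(drug = c("enzalutamide", sample(paste0("d", 1:50),
                                                   200, TRUE)),
                   gene = c("AR", sample(genes[-1], 200, TRUE)))
  out <- prioritize_drug_targets(r, dm, de)
  expect_identical(out$gene[1], "AR")
  expect_identical(out$compound[1], "enzalutamide")
  expect_equal(out$log2fc[1], 1.91)
  expect_lt(out$percentile_rank[1], 0.2)
  # brute-force oracle
  brute <- genes[r$percentile_rank[match(genes, r$gene)] <= 15 &
                   genes %in% dm$gene &
                   de$p < 0.05 & de$log2fc > log2(1.5)]
  expect_setequal(out$gene, brute)
  # gene at percentile 20 excluded even if otherwise qualifying
  g20 <- r$gene[which.min(abs(r$percentile_rank - 20))]
  de$p[de$gene == g20] <- 1e-9; de$log2fc[de$gene == g20] <- 3
  dm2 <- rbind(dm, data.frame(drug = "dx", gene = g20))
  expect_false(g20 %in% prioritize_drug_targets(r, dm2, de)$gene)
  expect_error(prioritize_drug_targets(r, dm[0, ], de), "empty")
})

test_that("combined pathway table orders by the truncated-product p", {
  assoc <- data.frame(pathway = c("A", "B", "C"), es = c(0.8, 0.5, 0.2),
                      p = c(0.001, 0.2, 0.04))
  dereg <- data.frame(pathway = c("A", "B", "C"), es = c(0.7, 0.1, 0.6),
                      p = c(0.01, 0.5, 0.03))
  out <- combine_pathway_results(assoc, dereg, tau = 0.05)
  expect_identical(out$pathway[1], "A")
  expect_true(all(diff(out$p_combined) >= 0))
  expect_equal(out$p_combined[out$pathway == "B"], 1)  # both above tau
  man <- truncated_product_combine(c(0.04, 0.03), 0.05)
  expect_equal(out$p_combined[out$pathway == "C"], man)
})
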