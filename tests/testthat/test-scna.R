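test_that("five-level encoding matches the printed map and is monotone", {
  expect_identical(encode_tcn(0), -2L)
  expect_identical(encode_tcn(2), 0L)
  expect_identical(encode_tcn(7), 2L)
  expect_identical(encode_tcn(0:6), c(-2L, -1L, 0L, 1L, 2L, 2L, 2L))
  expect_true(all(diff(encode_tcn(0:20)) >= 0))
  expect_error(encode_tcn(-1), "non-negative")
  expect_error(encode_tcn(1.5), "integer")
})

seg_row <- function(sample, chrom, start, end, log2, tcn = NA_integer_) {
  data.frame(sample = sample, chrom = as.character(chrom), start = start,
             end = end, num_mark = 10L, seg_mean = log2, tcn = tcn,
             stringsAsFactors = FALSE)
}

test_that("merge assigns the mean where samples overlap and keeps private segments", {
  p1 <- seg_row("s1", 1, 1, 100, 0.2)
  p2 <- seg_row("s2", 1, 1, 100, 0.4)
  m <- merge_patient_segments(list(s1 = p1, s2 = p2))
  expect_identical(nrow(m), 1L)
  expect_equal(m$seg_mean, 0.3)
  expect_identical(c(m$start, m$end), c(1L, 100L))
  # sample-specific segment emitted unchanged
  p3 <- rbind(seg_row("s3", 1, 1, 100, 0.1), seg_row("s3", 2, 1, 50, -0.8))
  m2 <- merge_patient_segments(list(s1 = p1, s3 = p3))
  expect_equal(m2$seg_mean[m2$chrom == "2"], -0.8)
})

test_that("merged intervals equal a per-base brute-force average on a toy chromosome", {
  set.seed(41)
  L <- 10000L
  make_profile <- function(id) {
    bk <- sort(sample(2:L, 4))
    starts <- c(1L, bk)
    ends <- c(bk - 1L, L)
    seg_row(id, 1, starts, ends, round(rnorm(5), 3))
  }
  profs <- list(a = make_profile("a"), b = make_profile("b"),
                c = make_profile("c"))
  merged <- merge_patient_segments(profs)
  # brute-force base-wise mean over covering samples
  base_vals <- matrix(NA_real_, L, 3)
  for (k in 1:3) {
    pr <- profs[[k]]
    for (r in seq_len(nrow(pr)))
      base_vals[pr$start[r]:pr$end[r], k] <- pr$seg_mean[r]
  }
  base_mean <- rowMeans(base_vals, na.rm = TRUE)
  for (r in seq_len(nrow(merged))) {
    span <- merged$start[r]:merged$end[r]
    expect_lt(max(abs(base_mean[span] - merged$seg_mean[r])), 1e-12)
  }
  # breakpoint-union length conservation (exact integers)
  expect_identical(as.integer(sum(merged$end - merged$start + 1)), L)
})

test_that("merge rejects overlapping segments within one sample", {
  bad <- rbind(seg_row("s1", 1, 1, 100, 0.1), seg_row("s1", 1, 50, 150, 0.2))
  expect_error(merge_patient_segments(list(s1 = bad)), "overlapping")
})

test_that("site-by-sample matrix rows derive from the covering segments", {
  p1 <- profile_from_arms("a")
  p2 <- profile_from_arms("b")
  sm <- segments_to_site_matrix(list(a = p1, b = p2), "encoded")
  expect_true(all(sm$mat[, "a"] == sm$mat[, "b"]))
  # private 6q loss differs in exactly one column
  p2l <- profile_from_arms("b", c("6q" = 1L))
  sm2 <- segments_to_site_matrix(list(a = p1, b = p2l), "encoded")
  diff_rows <- which(sm2$mat[, "a"] != sm2$mat[, "b"])
  expect_identical(length(diff_rows), 1L)
  arms <- hg19_arms()
  row_arm <- arms$arm[arms$chrom == sm2$intervals$chrom[diff_rows] &
                        arms$start == sm2$intervals$start[diff_rows]]
  expect_identical(row_arm, "6q")
  expect_equal(unname(sm2$mat[diff_rows, "b"]), -1)
})

test_that("simulated SCNA matrices reproduce truth events through the encoding", {
  cfg <- sim_config(n_patients = 1, seed = 55,
                    scna_rates = list(shared_gain = 0.3, shared_loss = 0.2,
                                      private = 0.2))
  set.seed(cfg$seed)
  sc <- simulate_scna_profiles(cfg, "P", c("Pa", "Pb", "Pc"))
  sm <- segments_to_site_matrix(sc$profiles, "encoded")
  arms <- hg19_arms()
  key <- paste(sm$intervals$chrom, sm$intervals$start)
  for (r in seq_len(nrow(sc$events))) {
    ev <- sc$events[r, ]
    row <- match(paste(arms$chrom[arms$arm == ev$arm],
                       arms$start[arms$arm == ev$arm]), key)
    if (ev$scope == "shared") {
      expect_true(all(sm$mat[row, ] == encode_tcn(ev$tcn)))
    } else {
      expect_equal(unname(sm$mat[row, ev$sample]),
                   as.numeric(encode_tcn(ev$tcn)))
      expect_true(all(sm$mat[row, setdiff(colnames(sm$mat),
                                          ev$sample)] == 0L))
    }
  }
})

test_that("SCNA trees separate shared from private events as hand-computed", {
  # all-diploid: star at germline, all distances 0
  sm0 <- segments_to_site_matrix(list(a = profile_from_arms("a"),
                                      b = profile_from_arms("b")),
                                 "encoded")
  t0 <- scna_tree(sm0)
  expect_true(all(t0$dist[c("a", "b"), c("a", "b")] == 0))
  # one shared gain: both at distance 1 from germline, 0 apart
  smg <- segments_to_site_matrix(
    list(a = profile_from_arms("a", c("1q" = 3L)),
         b = profile_from_arms("b", c("1q" = 3L))), "encoded")
  tg <- scna_tree(smg)
  expect_identical(unname(tg$dist["a", "germline"]), 1)
  expect_identical(unname(tg$dist["a", "b"]), 0)
  # 4 sites, 3 shared + 1 private: hand-computed distance table
  shared <- c("1q" = 3L, "5p" = 3L, "6q" = 1L)
  profs <- list(a = profile_from_arms("a", shared),
                b = profile_from_arms("b", shared),
                c = profile_from_arms("c", shared),
                d = profile_from_arms("d", c(shared, "17p" = 1L)))
  tm <- scna_tree(segments_to_site_matrix(profs, "encoded"))
  expect_identical(unname(tm$dist["a", "b"]), 0)
  expect_identical(unname(tm$dist["a", "d"]), 1)
  expect_identical(unname(tm$dist["a", "germline"]), 3)
  expect_identical(unname(tm$dist["d", "germline"]), 4)
  # trunk edge (germline to the samples' join) carries the 3 shared events
  cp <- stats::cophenetic(tm$tree)
  expect_equal(unname(cp["a", "germline"]), 3)
  expect_equal(unname(cp["d", "germline"]), 4)
  # log2-scale matrix is rejected
  sml <- segments_to_site_matrix(profs, "log2")
  expect_error(scna_tree(sml), "encoded")
})

test_that("recurrent gene calls honour the cutoff and minimum patient count", {
  genes <- toy_genes()
  g1q <- genes$gene[genes$arm == "1q"][1:3]
  g6q <- genes$gene[genes$arm == "6q"][1:2]
  mat <- matrix(0, 5, 14, dimnames = list(c(g1q, g6q),
                                          sprintf("P%02d", 1:14)))
  mat[g1q[1], 1:4] <- 0.3    # gain in exactly 4 patients -> recurrent
  mat[g1q[2], 1:3] <- 0.3    # 3 patients -> not recurrent
  mat[g1q[3], 1:4] <- 0.25   # boundary: >= 0.25 counts
  mat[g6q[1], 1:5] <- -0.3   # recurrent loss
  rec <- recurrent_scna_genes(mat)
  expect_setequal(rec$gain, c(g1q[1], g1q[3]))
  expect_identical(rec$loss, g6q[1])
  expect_length(rec$both, 0)
})

test_that("planted arm gains are recovered as recurrent genes across a cohort", {
  genes <- toy_genes()
  arms <- hg19_arms()
  patients <- sprintf("P%02d", 1:14)
  merged <- lapply(patients, function(pid) {
    tcn <- rep(2L, nrow(arms))
    names(tcn) <- arms$arm
    if (match(pid, patients) <= 8) tcn["1q"] <- 3L  # planted in 8/14
    data.frame(sample = pid, chrom = arms$chrom, start = arms$start,
               end = arms$end, num_mark = 10L,
               seg_mean = log2_from_tcn(tcn), stringsAsFactors = FALSE)
  })
  names(merged) <- patients
  gl <- cohort_gene_log2(merged, genes)
  rec <- recurrent_scna_genes(gl)
  expect_setequal(rec$gain, genes$gene[genes$arm == "1q"])
  expect_length(rec$loss, 0)
})

test_that("expression integration retains direction-concordant genes only", {
  rec <- list(gain = c("G1", "G2", "G3"), loss = c("G4", "G5"), both = c())
  de <- data.frame(gene = paste0("G", 1:6),
                   log2fc = c(0.9, 0.2, 1.2, -1.0, -0.7, 2.0),
                   p = c(0.01, 0.01, 0.2, 0.001, 0.03, 0.001))
  out <- integrate_with_expression(rec, de)
  expect_identical(out$gene[out$class == "up_gain"], "G1")   # FC 1.87, p .01
  expect_identical(out$gene[out$class == "down_loss"], c("G4", "G5"))
  # G2: FC 1.15 < 1.5; G3: p 0.2; G6 not recurrent
  expect_false(any(c("G2", "G3", "G6") %in% out$gene))
  # brute-force three-condition oracle
  brute_up <- de$gene[de$gene %in% rec$gain & de$p < 0.05 &
                        2^de$log2fc > 1.5]
  expect_setequal(out$gene[out$class == "up_gain"], brute_up)
  expect_error(integrate_with_expression(rec, rbind(de, de[1, ])),
               "duplicate")
})

test_that("intersample correlations match the textbook formula", {
  p1 <- profile_from_arms("a", c("1q" = 3L, "6q" = 1L))
  p2 <- profile_from_arms("b", c("1q" = 3L, "6q" = 1L))
  sm <- segments_to_site_matrix(list(a = p1, b = p2), "log2")
  expect_equal(intersample_correlation(sm)$r, 1)
  # negated column
  p3 <- p1; p3$sample <- "c"; p3$seg_mean <- -p1$seg_mean
  smn <- segments_to_site_matrix(list(a = p1, c = p3), "log2")
  expect_equal(intersample_correlation(smn)$r, -1)
  # random matrix vs direct covariance formula
  set.seed(61)
  sm$mat[, "a"] <- rnorm(nrow(sm$mat))
  sm$mat[, "b"] <- rnorm(nrow(sm$mat))
  r <- intersample_correlation(sm)$r
  x <- sm$mat[, "a"]; y <- sm$mat[, "b"]
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_lt(abs(r - r_direct), 1e-12)
  # zero variance reported missing
  sm$mat[, "a"] <- 0
  expect_true(is.na(intersample_correlation(sm)$r))
})
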