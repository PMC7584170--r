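test_that("probe filtering matches a brute-force enumeration of the rules", {
  set.seed(5)
  n <- 40; m <- 1000
  beta <- toy_beta(runif(n * m), m, n)
  detp <- toy_beta(runif(n * m, 0, 1e-3), m, n)
  beads <- toy_beta(sample(5:20, n * m, TRUE), m, n)
  # plant failures
  detp[sample(length(detp), 2000)] <- runif(2000, 0.06, 1)
  beads[sample(length(beads), 2000)] <- sample(1:2, 2000, TRUE)
  excl <- list(snp_list = sample(rownames(beta), 50),
               reactive = sample(rownames(beta), 30))
  th <- qc_thresholds()
  res <- filter_probes(beta, detp, beads, excl, th)
  # independent brute force, probe by probe
  fail_detp <- apply(detp, 1, function(x) mean(x > 0.05) > 0.05)
  fail_bead <- apply(beads, 1, function(x) mean(x < 3) >= 0.05)
  fail_excl <- rownames(beta) %in% unlist(excl)
  keep <- !(fail_detp | fail_bead | fail_excl)
  expect_identical(res$report$retained_probes, rownames(beta)[keep])
  expect_identical(rownames(res$beta), rownames(beta)[keep])
  # per-filter counts in the documented order
  expect_identical(res$report$filter_order[1:2], c("detection_p", "bead_count"))
  expect_equal(res$report$removed$n_removed[1], sum(fail_detp))
  expect_equal(res$report$removed$n_removed[2], sum(fail_bead & !fail_detp))
  expect_equal(res$report$n_retained + sum(res$report$removed$n_removed),
               res$report$n_input)
})

test_that("a probe failing detection-p in 6% of 100 samples is removed, clean probes retained", {
  m <- 3; n <- 100
  beta <- toy_beta(0.5, m, n)
  detp <- toy_beta(0, m, n)
  beads <- toy_beta(10, m, n)
  detp[1, 1:6] <- 0.2    # 6% > 5%: removed
  detp[2, 1:5] <- 0.2    # exactly 5%: retained (strict >)
  res <- suppressWarnings(filter_probes(beta, detp, beads))
  expect_false("cg001" %in% res$report$retained_probes)
  expect_true(all(c("cg002", "cg003") %in% res$report$retained_probes))
})

test_that("filtering is idempotent and robust to sample shuffling", {
  ch <- small_cohort()
  res1 <- filter_probes(ch$blood, ch$detp$blood, ch$beads$blood)
  res2 <- filter_probes(res1$beta,
                        ch$detp$blood[rownames(res1$beta), ],
                        ch$beads$blood[rownames(res1$beta), ])
  expect_equal(sum(res2$report$removed$n_removed), 0)
  perm <- sample(ncol(ch$blood))
  res3 <- filter_probes(ch$blood[, perm], ch$detp$blood[, perm],
                        ch$beads$blood[, perm])
  expect_identical(res1$report$retained_probes, res3$report$retained_probes)
  # missing matrices skip their filters with a warning
  expect_warning(filter_probes(ch$blood, detp = NULL, beads = ch$beads$blood),
                 "detection-p")
  expect_error(filter_probes(ch$blood, ch$detp$blood[, 1:3], ch$beads$blood),
               "shape")
})

test_that("a sample displaced on all probes is flagged by PC1 and robust-distance rules", {
  set.seed(9)
  n <- 21; m <- 400
  beta <- toy_beta(runif(n * m, 0.3, 0.5), m, n)
  beta[, 7] <- pmin(beta[, 7] + 0.3, 1)
  out <- detect_outlier_samples(beta)
  expect_identical(out$sample[out$outlier], "s07")
  # brute-force PCA check of the PC1 rule on the same matrix
  sc <- prcomp(t(beta), center = TRUE)$x[, 1]
  manual <- abs(sc - median(sc)) > 2 * IQR(sc)
  expect_identical(unname(manual), out$pc1_iqr)
  # label-permutation invariance
  perm <- sample(n)
  out2 <- detect_outlier_samples(beta[, perm])
  expect_setequal(out$sample[out$outlier], out2$sample[out2$outlier])
})

test_that("near-identical samples produce no outlier flags; constant matrix warns", {
  set.seed(10)
  beta <- toy_beta(0.4 + rnorm(300 * 12, 0, 1e-3), 300, 12)
  out <- detect_outlier_samples(beta)
  expect_false(any(out$outlier))
  flat <- toy_beta(0.4, 50, 6)
  expect_warning(res <- detect_outlier_samples(flat), "constant")
  expect_false(any(res$outlier))
})

test_that("type-stratified quantile normalization matches its definition", {
  set.seed(11)
  m <- 200
  types <- sample(c("I", "II"), m, TRUE)
  a <- runif(m, 0, 0.98)   # keep a + 0.01 inside [0,1]: no clipping ties
  beta <- cbind(s1 = a, s2 = a + 0.01)
  rownames(beta) <- sprintf("cg%03d", 1:m)
  norm <- normalize_betas(beta, types)
  for (tp in c("I", "II")) {
    rows <- types == tp
    # identical sorted profiles per stratum across samples
    expect_equal(sort(norm[rows, 1]), sort(norm[rows, 2]), tolerance = 1e-12)
    # within-sample, within-stratum ranks preserved
    for (j in 1:2) {
      expect_equal(cor(rank(beta[rows, j]), rank(norm[rows, j]),
                       method = "spearman"), 1)
    }
    # value multisets are shared across samples exactly
  }
  expect_true(all(norm >= 0 & norm <= 1))
  # single sample: unchanged
  one <- normalize_betas(beta[, 1, drop = FALSE], types)
  expect_equal(unname(one[, 1]), unname(beta[, 1]))
  expect_error(normalize_betas(beta, rep("weird", m)), "unknown probe type")
})

test_that("genotype concordance separates matched from mismatched pairs", {
  set.seed(12)
  n_probes <- 59
  g_a <- rbinom(n_probes, 2, 0.4) / 2
  g_b <- rbinom(n_probes, 2, 0.4) / 2
  blood <- cbind(p1 = g_a, p2 = g_b, p3 = rep(0.5, n_probes))
  sperm <- cbind(p1 = g_a,              # same individual
                 p2 = rbinom(n_probes, 2, 0.4) / 2,  # independent genotypes
                 p3 = rep(0.5, n_probes))            # constant: indeterminate
  rownames(blood) <- rownames(sperm) <- sprintf("rs%02d", 1:n_probes)
  res <- check_genotype_concordance(blood, sperm)
  expect_identical(res$verdict, c("concordant", "discordant", "indeterminate"))
  expect_equal(res$r[1], 1)
  expect_lt(abs(res$r[2]), 0.5)
  expect_error(
    check_genotype_concordance(blood, sperm,
                               tibble::tibble(blood = "p9", sperm = "p1")),
    "absent")
})
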