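test_that("variable-site selection applies the inclusive middle-80% range rule", {
  # constructed 20-sample vector with 10-90 percentile range exactly 0.05
  x <- seq(0.40, 0.4625, length.out = 20)
  rng <- unname(diff(quantile(x, c(0.1, 0.9), type = 7)))
  stopifnot(abs(rng - 0.05) < 1e-12)
  blood <- rbind(x, rep(0.5, 20), x)
  sperm <- rbind(x, x, rep(0.5, 20))
  rownames(blood) <- rownames(sperm) <- c("both_ok", "flat_blood", "flat_sperm")
  colnames(blood) <- colnames(sperm) <- sprintf("s%02d", 1:20)
  # inclusive boundary: a range exactly equal to min_range is kept
  keep <- select_variable_sites(blood, sperm, min_range = rng)
  expect_identical(keep, "both_ok")   # range exactly 0.05 kept; constants dropped
  # monotone: raising min_range never adds probes
  k1 <- select_variable_sites(blood, sperm, min_range = 0.04)
  k2 <- select_variable_sites(blood, sperm, min_range = 0.06)
  expect_true(all(k2 %in% k1))
  # sample-order invariance
  perm <- sample(20)
  expect_identical(select_variable_sites(blood[, perm], sperm[, perm],
                                         min_range = rng), keep)
})

test_that("per-site correlation matches the textbook formulas", {
  set.seed(51)
  n <- 10
  x <- runif(n, 0.2, 0.8)
  y <- pmin(pmax(0.5 * x + rnorm(n, 0, 0.05), 0), 1)
  blood <- rbind(x, x, x)
  sperm <- rbind(y, 1 - x, rep(0.4, n))
  rownames(blood) <- rownames(sperm) <- c("noisy", "anti", "flat")
  colnames(blood) <- colnames(sperm) <- sprintf("s%02d", 1:n)
  res <- correlate_sites(blood, sperm)
  ct <- cor.test(x, y)
  row <- res[res$probe_id == "noisy", ]
  expect_equal(row$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(row$p.value, ct$p.value, tolerance = 1e-12)
  expect_equal(res$r[res$probe_id == "anti"], -1, tolerance = 1e-12)
  expect_true(is.na(res$r[res$probe_id == "flat"]))
  expect_true(res$negative[res$probe_id == "anti"])
  # sperm = blood: r = 1 at every non-constant probe
  self <- correlate_sites(blood, blood)
  expect_equal(self$r, rep(1, 3), tolerance = 1e-12)
})

test_that("permutation null has Fisher-z SD near 1/sqrt(n-3) and is seed-reproducible", {
  cfg <- null_config(n_individuals = 40, n_probes = 150, seed = 61)
  ch <- generate_cohort(cfg)
  pn <- permutation_null(ch$blood, ch$sperm, n_perm = 100, seed = 7)
  expect_gte(length(pn$r), 1e4)
  z_sd <- glance(pn)$sd_fisher_z
  expect_lt(abs(z_sd - 1 / sqrt(40 - 3)), 0.1 / sqrt(40 - 3))
  # determinism and the empty case
  pn2 <- permutation_null(ch$blood, ch$sperm, n_perm = 100, seed = 7)
  expect_identical(pn$r, pn2$r)
  pn0 <- permutation_null(ch$blood, ch$sperm, n_perm = 0, seed = 7)
  expect_length(pn0$r, 0)
})

test_that("modality clustering calls planted geometries correctly", {
  set.seed(71)
  # trimodal: 15 points per corner cluster, jitter sd 0.02
  centers <- c(0.05, 0.5, 0.95)
  b <- rep(centers, each = 15) + rnorm(45, 0, 0.02)
  s <- rep(centers, each = 15) + rnorm(45, 0, 0.02)
  res <- classify_modality_kmeans(pmin(pmax(b, 0), 1), pmin(pmax(s, 0), 1))
  expect_identical(res$modality, "trimodal")
  expect_false(res$outlier_driven)
  # single isotropic blob
  blob <- classify_modality_kmeans(rnorm(40, 0.5, 0.03), rnorm(40, 0.5, 0.03))
  expect_identical(blob$modality, "unimodal")
  # 40 points + 1 displaced: bimodal, outlier-driven
  b2 <- c(rnorm(40, 0.1, 0.02), 0.9)
  s2 <- c(rnorm(40, 0.1, 0.02), 0.9)
  out <- classify_modality_kmeans(pmax(b2, 0), pmax(s2, 0))
  expect_identical(out$modality, "bimodal")
  expect_true(out$outlier_driven)
  # indeterminate below 8 points
  tiny <- classify_modality_kmeans(runif(5), runif(5))
  expect_identical(tiny$modality, "indeterminate")
})

test_that("gap hunting equals a brute-force sort-and-split and flags small groups", {
  cfg <- modality_config()
  # three tight bands
  v3 <- c(rnorm(20, 0.10, 0.005), rnorm(20, 0.50, 0.005), rnorm(20, 0.90, 0.005))
  res3 <- gap_hunt(v3, cfg)
  expect_identical(res3$modality, "trimodal")
  expect_equal(res3$n_groups, 3L)
  # 46 + 1 outlier
  v2 <- c(rnorm(46, 0.10, 0.005), 0.9)
  res2 <- gap_hunt(v2, cfg)
  expect_equal(res2$n_groups, 2L)
  expect_true(res2$outlier_driven)
  # all within a 0.04 span
  expect_equal(gap_hunt(runif(30, 0.5, 0.54), cfg)$n_groups, 1L)
  # randomized instances vs brute force
  set.seed(81)
  for (i in 1:20) {
    v <- runif(sample(5:40, 1))
    got <- gap_hunt(v, cfg)
    srt <- sort(v)
    n_brute <- 1L + sum(diff(srt) > cfg$gap_cutoff)
    expect_equal(got$n_groups, n_brute)
    # group ids must be monotone in value
    expect_identical(order(tapply(v, got$groups[[1]], min)),
                     seq_len(n_brute))
  }
})

test_that("planted SNP classes are recovered by both modality methods at cohort scale", {
  ch <- small_cohort()
  tri <- probes_of_class(ch, "snp_trimodal")
  calls <- classify_correlated_sites(ch$blood, ch$sperm, tri)
  expect_gte(mean(calls$modality_kmeans == "trimodal"), 0.9)
  expect_gte(mean(calls$modality_gap_blood == "trimodal"), 0.9)
  expect_gte(mean(calls$modality_gap_sperm == "trimodal"), 0.9)
  outp <- probes_of_class(ch, "outlier_driven")
  oc <- classify_correlated_sites(ch$blood, ch$sperm, outp)
  expect_gte(mean(oc$outlier_driven_kmeans), 0.9)
  expect_gte(mean(oc$outlier_driven_gap_blood), 0.9)
  neg <- probes_of_class(ch, "negative_correlated")
  cr <- correlate_sites(ch$blood[neg, , drop = FALSE], ch$sperm[neg, , drop = FALSE])
  expect_true(all(cr$r < 0))
  expect_true(all(cr$significant))
})

test_that("SNP position annotation applies the chemistry-specific rules", {
  ann <- tibble::tibble(
    probe_id = c("p1", "p2", "p3", "p4", "p5"),
    probe_type = c("II", "II", "I", "I", "II"),
    snp_offsets = list(0L, c(2L, 30L), -1L, c(5L, -3L), NULL)
  )
  res <- annotate_snps(ann)
  expect_identical(res$snp_category,
                   c("cpg_site", "probe_body", "single_base_extension",
                     "probe_body", "none"))
  expect_equal(res$snp_distance, c(0, 2, 1, 3, Inf))
  bad <- tibble::tibble(probe_id = "px", probe_type = "II", snp_offsets = list(60L))
  expect_error(annotate_snps(bad), "px")
})

test_that("genetic enrichment reconstructs the 2x2 table and handles restriction", {
  # equal prevalence: OR = 1
  correlated <- sprintf("c%02d", 1:20)
  background <- sprintf("b%03d", 1:100)
  flags <- c(correlated[1:2], background[1:10])
  res <- genetic_enrichment(correlated, background, flags)
  expect_equal(res$odds_ratio, (2 * 90) / (18 * 10))
  # counts (33, 1480, 307, 153449): OR ~ 11.1, tiny p
  big_cor <- sprintf("c%05d", 1:1513)
  big_bg <- sprintf("g%06d", 1:153756)
  big_flags <- c(big_cor[1:33], big_bg[1:307])
  res2 <- genetic_enrichment(big_cor, big_bg, big_flags)
  expect_equal(res2$a, 33); expect_equal(res2$c, 307)
  expect_equal(res2$odds_ratio, (33 * 153449) / (1480 * 307), tolerance = 1e-12)
  expect_lt(res2$p, 1e-20)
  # restriction to the flag-defined sub-array
  res3 <- genetic_enrichment(correlated, background, flags,
                             restrict_to = c(correlated[1:10], background[1:50]))
  expect_equal(res3$a + res3$b, 10)
  expect_error(genetic_enrichment(correlated, correlated[1], flags), "disjoint")
})

test_that("no correlations pass the array-wide threshold on independent tissues", {
  for (seed in 1:3) {
    ch <- generate_cohort(null_config(n_individuals = 20, n_probes = 2000,
                                      seed = seed, noise_sd = 0.03))
    cr <- correlate_sites(ch$blood, ch$sperm)
    expect_equal(sum(cr$significant), 0)
  }
})
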