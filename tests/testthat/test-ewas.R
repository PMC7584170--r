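test_that("cell-composition estimation solves exact and noisy mixtures", {
  cfg <- sim_config(n_individuals = 8, n_obese = 0, noise_sd = 0, seed = 91)
  ref <- generate_reference_profiles(cfg, n_celltypes = 3)
  # sample equal to a reference column
  beta <- cbind(ref$reference[, 2], ref$reference[, 3])
  colnames(beta) <- c("sA", "sB")
  est <- estimate_cell_composition(beta, ref$reference)
  expect_equal(unname(unlist(est[1, colnames(ref$reference)])),
               c(0, 1, 0), tolerance = 1e-8)
  # noise-free 0.5/0.5 mixture of two profiles
  mix <- 0.5 * ref$reference[, 1] + 0.5 * ref$reference[, 2]
  est2 <- estimate_cell_composition(cbind(m = mix), ref$reference)
  expect_equal(unname(unlist(est2[1, colnames(ref$reference)])),
               c(0.5, 0.5, 0), tolerance = 1e-8)
  # rank-deficient reference errors
  bad_ref <- cbind(ref$reference, dup = ref$reference[, 1])
  expect_error(estimate_cell_composition(beta, bad_ref), "rank")
})

test_that("six-type Dirichlet mixtures are recovered within 0.05 MAE", {
  cfg <- sim_config(n_individuals = 40, n_obese = 0, noise_sd = 0.02, seed = 92)
  ref <- generate_reference_profiles(cfg, n_celltypes = 6)
  est <- estimate_cell_composition(ref$beta, ref$reference)
  mae <- mean(abs(as.matrix(est[, colnames(ref$reference)]) - ref$fractions))
  expect_lt(mae, 0.05)
})

test_that("single-tissue EWAS equals the normal-equations oracle on a tiny design", {
  set.seed(93)
  n <- 6
  cov <- data.frame(obesity = c(0, 0, 0, 1, 1, 1), age = rnorm(n, 35, 5))
  beta <- toy_beta(runif(3 * n), 3, n)
  res <- ewas_single_tissue(beta, cov)
  X <- cbind(1, cov$obesity, cov$age)
  for (i in 1:3) {
    b_hat <- solve(t(X) %*% X, t(X) %*% beta[i, ])
    expect_equal(res$effect[i], b_hat[2], tolerance = 1e-10)
    sm <- summary(lm(beta[i, ] ~ obesity + age, data = cov))$coefficients
    expect_equal(res$se[i], sm["obesity", 2], tolerance = 1e-10)
    expect_equal(res$p.value[i], sm["obesity", 4], tolerance = 1e-10)
  }
  # collinear design errors with the offending column named
  cov_bad <- data.frame(obesity = cov$obesity, twin = cov$obesity)
  expect_error(ewas_single_tissue(beta, cov_bad), "collinear")
})

test_that("planted obesity shift is recovered by single-tissue and mixed models", {
  cfg <- sim_config(n_individuals = 43, n_probes = 400, n_obese = 15,
                    class_fractions = c(obesity_associated = 0.125),
                    noise_sd = 0.01, seed = 94)
  ch <- generate_cohort(cfg)
  cov <- ch$sample_sheet[, c("obesity", "age", "batch")]
  ob <- probes_of_class(ch, "obesity_associated")
  res <- ewas_single_tissue(ch$blood, cov)
  est <- res$effect[res$probe_id %in% ob]
  expect_gt(mean(est), 0.015)
  expect_lt(mean(est), 0.025)
  # sign convention: positive = higher methylation in obese
  expect_gt(mean(est > 0), 0.95)
  mixed <- ewas_mixed(ch$blood, ch$sperm, cov)
  est_m <- mixed$effect[mixed$probe_id %in% ob]
  expect_gt(mean(est_m), 0.015)
  expect_lt(mean(est_m), 0.025)
})

test_that("the balanced mixed-model path agrees with lmerTest and collapses at the boundary", {
  cfg <- sim_config(n_individuals = 24, n_probes = 15, n_obese = 8,
                    noise_sd = 0.01, seed = 95)
  ch <- generate_cohort(cfg)
  cov <- ch$sample_sheet[, c("obesity", "age", "batch")]
  fast <- ewas_mixed(ch$blood, ch$sperm, cov, method = "anova")
  slow <- ewas_mixed(ch$blood, ch$sperm, cov, method = "lmer")
  expect_equal(fast$effect, slow$effect, tolerance = 1e-8)
  nb <- !fast$boundary
  expect_equal(fast$se[nb], slow$se[nb], tolerance = 1e-6)
  expect_equal(fast$df[nb], slow$df[nb], tolerance = 1e-3)
  expect_equal(fast$p.value, slow$p.value, tolerance = 1e-5)
  # zero random-intercept variance: mixed estimates equal pooled OLS
  cfg0 <- null_config(n_individuals = 16, n_probes = 30, seed = 96,
                      individual_sd = 0, n_obese = 5)
  ch0 <- generate_cohort(cfg0)
  cov0 <- ch0$sample_sheet[, c("obesity", "age", "batch")]
  mix0 <- ewas_mixed(ch0$blood, ch0$sperm, cov0)
  stacked <- cbind(ch0$blood, ch0$sperm)
  colnames(stacked) <- sprintf("s%02d", seq_len(ncol(stacked)))
  cov_pool <- rbind(cov0, cov0)
  cov_pool$tissue <- rep(c(0, 1), each = 16)
  pool <- ewas_single_tissue(stacked, cov_pool)
  b <- mix0$boundary
  expect_gt(sum(b), 0)
  expect_equal(mix0$effect[b], pool$effect[b], tolerance = 1e-10)
  expect_equal(mix0$p.value[b], pool$p.value[b], tolerance = 1e-10)
})

test_that("interaction scan matches the normal equations and recovers a planted slope change", {
  set.seed(97)
  n <- 8
  obesity <- c(0, 0, 0, 0, 1, 1, 1, 1)
  age <- rnorm(n, 35, 4)
  sperm <- toy_beta(runif(2 * n, 0.2, 0.8), 2, n)
  blood <- sperm
  blood[1, ] <- 0.1 + 0.2 * sperm[1, ] + 0.5 * sperm[1, ] * obesity +
    rnorm(n, 0, 0.01)
  blood[2, ] <- 0.3 + 0.4 * sperm[2, ]     # identical slope in both groups
  covs <- data.frame(obesity = obesity, age = age)
  res <- interaction_scan(blood, sperm, covs, loo_diagnostic = FALSE)
  x <- sperm[1, ]; y <- blood[1, ]
  fit <- summary(lm(y ~ x * obesity + age))$coefficients
  expect_equal(res$effect[1], fit["x:obesity", 1], tolerance = 1e-10)
  expect_equal(res$p.value[1], fit["x:obesity", 4], tolerance = 1e-10)
  # identical slope in both groups, no noise: interaction coefficient is zero
  expect_equal(res$effect[2], 0, tolerance = 1e-8)
  # larger cohort: planted interaction 0.5 recovered within [0.4, 0.6]
  n2 <- 60
  ob2 <- rep(c(0, 1), each = 30)
  sp2 <- toy_beta(runif(20 * n2, 0.2, 0.8), 20, n2)
  bl2 <- 0.05 + 0.3 * sp2 + 0.5 * sweep(sp2, 2, ob2, "*") +
    matrix(rnorm(20 * n2, 0, 0.01), 20, n2)
  dimnames(bl2) <- dimnames(sp2)
  res2 <- interaction_scan(bl2, sp2, data.frame(obesity = ob2), alpha = 1e-4)
  expect_true(all(res2$effect > 0.4 & res2$effect < 0.6))
  # leave-one-out diagnostic present for significant probes
  expect_true(all(is.finite(res2$loo_max_t_change[res2$significant])))
})

test_that("prior-probe enrichment matches exact rank-sum enumeration and calibrates", {
  # prior set holds exactly the 3 smallest p-values among 10
  res_tbl <- tibble::tibble(probe_id = sprintf("cg%02d", 1:10),
                            p.value = seq(0.01, 0.95, length.out = 10))
  pri <- res_tbl$probe_id[1:3]
  enr <- prior_probe_enrichment(res_tbl, pri)
  # exact two-sided p by enumeration over all C(10,3) assignments of ranks
  combs <- utils::combn(10, 3)
  w_obs <- sum(1:3) - 6      # Mann-Whitney U of the prior group = 0
  u_all <- colSums(combs) - 6
  p_exact <- mean(u_all <= w_obs) * 2
  expect_equal(enr$p.value, p_exact, tolerance = 1e-12)
  # calibration: uniform p-values in and out of the prior set
  set.seed(98)
  reps <- replicate(400, {
    tb <- tibble::tibble(probe_id = sprintf("cg%03d", 1:120),
                         p.value = runif(120))
    prior_probe_enrichment(tb, tb$probe_id[1:20])$p.value
  })
  ks <- suppressWarnings(ks.test(reps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("effect concordance is invariant under monotone transforms", {
  set.seed(99)
  loc <- tibble::tibble(probe_id = sprintf("cg%02d", 1:30), effect = rnorm(30))
  pri <- tibble::tibble(probe_id = loc$probe_id, effect = exp(2 * loc$effect))
  res <- effect_concordance(loc, pri)
  expect_equal(res$rho, 1)
  expect_error(effect_concordance(loc[1:2, ], pri[5:6, ]), "shared")
})
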