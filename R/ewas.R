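#' Reference-based cell-composition estimation
#'
#' Estimates per-sample cell-type fractions from blood methylation by
#' constrained projection onto reference profiles: non-negative least squares
#' per sample over the reference probes, followed by rescaling onto the
#' simplex when the non-negative solution sums above 1. This is the standard
#' reference-based deconvolution approach for whole blood (monocytes,
#' granulocytes, NK cells, B cells, CD8+ and CD4+ T cells in the usual
#' six-type reference).
#'
#' @param beta_blood Probe x sample beta matrix; must contain the reference
#'   probes.
#' @param reference Reference matrix (probes x cell types) with rownames
#'   matching probes of `beta_blood`.
#' @return Tibble: `sample`, one fraction column per cell type, and
#'   `residual` (root-mean-square residual of the constrained fit).
#' @export
estimate_cell_composition <- function(beta_blood, reference) {
  assert_beta_matrix(beta_blood, "beta_blood")
  reference <- as.matrix(reference)
  if (ncol(reference) < 1) stop("need at least one cell type", call. = FALSE)
  missing <- setdiff(rownames(reference), rownames(beta_blood))
  if (length(missing)) {
    stop("reference probes absent from `beta_blood`: ",
         paste(head(missing, 5), collapse = ", "), call. = FALSE)
  }
  if (qr(reference)$rank < ncol(reference)) {
    stop("reference profiles are rank-deficient; cell types are not distinguishable",
         call. = FALSE)
  }
  B <- beta_blood[rownames(reference), , drop = FALSE]
  types <- colnames(reference)
  out <- purrr::map(seq_len(ncol(B)), function(j) {
    fit <- pracma::lsqnonneg(reference, B[, j])
    f <- fit$x
    if (sum(f) > 1) f <- f / sum(f)
    rmse <- sqrt(mean((B[, j] - reference %*% f)^2))
    row <- tibble::as_tibble(as.list(setNames(f, types)))
    row$sample <- colnames(B)[j]
    row$residual <- rmse
    row
  })
  dplyr::bind_rows(out) |>
    dplyr::relocate("sample")
}

build_design <- function(covariates, predictor) {
  covariates <- as.data.frame(covariates)
  if (!predictor %in% names(covariates)) {
    stop("predictor `", predictor, "` not found among covariates", call. = FALSE)
  }
  X <- model.matrix(~ ., data = covariates)
  term <- grep(paste0("^", predictor), colnames(X), value = TRUE)
  if (length(term) != 1) {
    stop("predictor `", predictor, "` must map to a single design column",
         call. = FALSE)
  }
  list(X = X, term = term)
}

#' Single-tissue EWAS by ordinary least squares
#'
#' Regresses methylation at every probe on a phenotype (obesity indicator or
#' continuous BMI) plus covariates, sharing one design matrix across probes.
#' The effect is the predictor coefficient on the beta scale with lean/
#' reference coded 0, so a positive effect means higher methylation in the
#' exposed group.
#'
#' @param beta Probe x sample beta matrix.
#' @param covariates Data frame with one row per sample (in column order of
#'   `beta`) holding the predictor and adjustment covariates, e.g. obesity,
#'   age, batch and estimated cell fractions for blood. Factors are expanded
#'   via `model.matrix`; for compositional cell fractions supply all but one
#'   type to avoid collinearity.
#' @param predictor Name of the covariate whose coefficient is reported.
#' @param alpha Significance threshold (default `9e-8`).
#' @return Tibble of class `ewas_result`: `probe_id`, `effect`, `se`,
#'   `statistic`, `df`, `p.value`, `significant`, `model`.
#' @export
ewas_single_tissue <- function(beta, covariates, predictor = "obesity",
                               alpha = 9e-8) {
  assert_beta_matrix(beta)
  if (nrow(covariates) != ncol(beta)) {
    stop("`covariates` must have one row per sample", call. = FALSE)
  }
  dn <- build_design(covariates, predictor)
  fit <- ols_scan(dn$X, t(beta), dn$term)
  res <- tibble::tibble(
    probe_id = rownames(beta),
    effect = fit$estimate,
    se = fit$se,
    statistic = fit$statistic,
    df = fit$df,
    p.value = fit$p.value,
    significant = fit$p.value < alpha,
    model = "single_tissue_ols"
  )
  new_crossmeth_result(res, "ewas_result", alpha = alpha)
}

# Exact REML decomposition of the random-intercept model for balanced
# complete pairs: within stratum (sperm - blood differences) estimates the
# tissue effect and the residual variance; between stratum (pair means)
# estimates the individual-level covariates with variance tau^2 + sigma^2/2.
# For a purely between-individual predictor the Wald t with Satterthwaite df
# equals the between-stratum OLS t on n - p df. Negative tau^2 estimates hit
# the boundary, where the REML fit collapses to pooled OLS.
mixed_scan_balanced <- function(blood, sperm, X_b, term, alpha) {
  n <- ncol(blood)
  D <- t(sperm - blood)              # n x probes
  M <- t(sperm + blood) / 2
  sigma2 <- matrixStats::colVars(D) / 2
  between <- ols_scan(X_b, M, term)
  p_b <- ncol(X_b)
  s2_between <- {
    qrX <- qr(X_b)
    res <- M - X_b %*% qr.coef(qrX, M)
    colSums(res^2) / (n - p_b)
  }
  tau2 <- s2_between - sigma2 / 2
  boundary <- tau2 < 0
  out <- tibble::tibble(
    probe_id = colnames(D),
    effect = between$estimate,
    se = between$se,
    statistic = between$statistic,
    df = between$df,
    p.value = between$p.value,
    sigma_individual = sqrt(pmax(tau2, 0)),
    sigma_residual = sqrt(sigma2),
    boundary = boundary,
    converged = TRUE
  )
  if (any(boundary)) {
    # pooled OLS on the stacked observations with a tissue indicator
    X_pool <- rbind(cbind(X_b, tissue = 0), cbind(X_b, tissue = 1))
    Y_pool <- rbind(t(blood[out$probe_id[boundary], , drop = FALSE]),
                    t(sperm[out$probe_id[boundary], , drop = FALSE]))
    pooled <- ols_scan(X_pool, Y_pool, term)
    out$effect[boundary] <- pooled$estimate
    out$se[boundary] <- pooled$se
    out$statistic[boundary] <- pooled$statistic
    out$df[boundary] <- pooled$df
    out$p.value[boundary] <- pooled$p.value
  }
  out$significant <- out$p.value < alpha
  out$model <- "mixed_random_intercept"
  out
}

#' Cross-tissue EWAS with a random intercept per individual
#'
#' Fits, per probe, the linear mixed model
#' `methylation ~ tissue + age + batch + obesity + (1 | individual)`
#' by REML across both tissues' samples, reporting the obesity (or other
#' between-individual predictor) coefficient with a Wald test on
#' Satterthwaite-approximated degrees of freedom.
#'
#' For the balanced design (every individual observed exactly once per
#' tissue; predictor and covariates constant within individual) the REML fit
#' decomposes exactly into within-pair and between-pair ordinary regressions,
#' which is used as a fast vectorized path; `method = "lmer"` forces the
#' general per-probe \pkg{lmerTest} route, which is also the fallback whenever
#' the design is not balanced.
#'
#' @param beta_blood,beta_sperm Probe x individual beta matrices with matching
#'   column order (one column per individual).
#' @param covariates Data frame, one row per individual: the predictor plus
#'   individual-level covariates (e.g. obesity, age, batch).
#' @param predictor Covariate whose coefficient is reported (default
#'   `"obesity"`).
#' @param alpha Significance threshold (default `9e-8`).
#' @param method `"auto"` (fast exact path for the balanced design),
#'   `"anova"` (force the decomposition), or `"lmer"`.
#' @return Tibble of class `ewas_result`: `probe_id`, `effect`, `se`,
#'   `statistic`, `df`, `p.value`, `sigma_individual`, `sigma_residual`,
#'   `boundary` (random-intercept variance hit zero), `converged`,
#'   `significant`, `model`.
#' @export
ewas_mixed <- function(beta_blood, beta_sperm, covariates,
                       predictor = "obesity", alpha = 9e-8,
                       method = c("auto", "anova", "lmer")) {
  method <- match.arg(method)
  assert_beta_matrix(beta_blood, "beta_blood")
  assert_beta_matrix(beta_sperm, "beta_sperm")
  probes <- intersect(rownames(beta_blood), rownames(beta_sperm))
  blood <- beta_blood[probes, , drop = FALSE]
  sperm <- beta_sperm[probes, , drop = FALSE]
  if (!identical(ncol(blood), ncol(sperm))) {
    stop("tissue matrices must cover the same individuals", call. = FALSE)
  }
  if (nrow(covariates) != ncol(blood)) {
    stop("`covariates` must have one row per individual", call. = FALSE)
  }
  dn <- build_design(covariates, predictor)
  if (method %in% c("auto", "anova")) {
    res <- mixed_scan_balanced(blood, sperm, dn$X, dn$term, alpha)
    return(new_crossmeth_result(res, "ewas_result", alpha = alpha))
  }
  ## general route: per-probe lmerTest fit on the stacked long data
  long_cov <- as.data.frame(covariates)[rep(seq_len(ncol(blood)), 2), , drop = FALSE]
  long_cov$tissue <- rep(c("blood", "sperm"), each = ncol(blood))
  long_cov$individual <- rep(colnames(blood) %||% as.character(seq_len(ncol(blood))), 2)
  fml <- stats::as.formula(paste(
    "y ~ tissue +",
    paste(setdiff(names(covariates), NULL), collapse = " + "),
    "+ (1 | individual)"))
  out <- purrr::map(probes, function(pr) {
    dat <- long_cov
    dat$y <- c(blood[pr, ], sperm[pr, ])
    fit <- tryCatch(
      lmerTest::lmer(fml, data = dat,
                     control = lme4::lmerControl(check.conv.singular = "ignore")),
      error = function(e) NULL)
    if (is.null(fit)) {
      return(tibble::tibble(
        probe_id = pr, effect = NA_real_, se = NA_real_,
        statistic = NA_real_, df = NA_real_, p.value = NA_real_,
        sigma_individual = NA_real_, sigma_residual = NA_real_,
        boundary = NA, converged = FALSE))
    }
    cf <- stats::coef(summary(fit))
    row <- grep(paste0("^", predictor), rownames(cf))[1]
    vc <- as.data.frame(lme4::VarCorr(fit))
    tibble::tibble(
      probe_id = pr,
      effect = cf[row, "Estimate"],
      se = cf[row, "Std. Error"],
      statistic = cf[row, "t value"],
      df = cf[row, "df"],
      p.value = cf[row, "Pr(>|t|)"],
      sigma_individual = vc$sdcor[vc$grp == "individual"],
      sigma_residual = vc$sdcor[vc$grp == "Residual"],
      boundary = vc$sdcor[vc$grp == "individual"] < 1e-8,
      converged = TRUE
    )
  }) |> dplyr::bind_rows()
  out$significant <- !is.na(out$p.value) & out$p.value < alpha
  out$model <- "mixed_random_intercept"
  new_crossmeth_result(out, "ewas_result", alpha = alpha)
}

#' Scan for obesity-by-sperm interaction on blood methylation
#'
#' Per probe, fits `blood ~ sperm * obesity + age + batch` (ordinary least
#' squares) and reports the interaction coefficient: does obesity alter the
#' association between sperm and blood methylation at this site? For probes
#' passing `alpha`, a leave-one-out diagnostic reports the maximal change in
#' the interaction t statistic when a single pair is dropped, to expose
#' interactions carried by individual outliers.
#'
#' @param beta_blood,beta_sperm Probe x individual beta matrices with matching
#'   column order.
#' @param covariates Data frame, one row per individual, containing the
#'   `interaction_with` column (0/1 obesity indicator) and adjustment
#'   covariates.
#' @param interaction_with Name of the grouping covariate (default
#'   `"obesity"`).
#' @param alpha Significance threshold (default `9e-8`).
#' @param loo_diagnostic Compute the leave-one-out diagnostic for significant
#'   probes (default `TRUE`).
#' @return Tibble of class `ewas_result`: `probe_id`, `effect` (interaction
#'   coefficient), `se`, `statistic`, `df`, `p.value`, `significant`,
#'   `loo_max_t_change` (NA where not computed), `model`.
#' @export
interaction_scan <- function(beta_blood, beta_sperm, covariates,
                             interaction_with = "obesity", alpha = 9e-8,
                             loo_diagnostic = TRUE) {
  assert_beta_matrix(beta_blood, "beta_blood")
  assert_beta_matrix(beta_sperm, "beta_sperm")
  probes <- intersect(rownames(beta_blood), rownames(beta_sperm))
  n <- ncol(beta_blood)
  if (nrow(covariates) != n) {
    stop("`covariates` must have one row per individual", call. = FALSE)
  }
  covariates <- as.data.frame(covariates)
  g <- covariates[[interaction_with]]
  if (is.null(g)) stop("column `", interaction_with, "` not found", call. = FALSE)
  others <- setdiff(names(covariates), interaction_with)
  X_other <- if (length(others)) {
    model.matrix(~ ., data = covariates[others])[, -1, drop = FALSE]
  } else {
    matrix(numeric(0), n, 0)
  }
  p_full <- 4 + ncol(X_other)
  if (n < p_full + 1) {
    stop("fewer pairs than coefficients + 1; interaction model undefined",
         call. = FALSE)
  }
  fit_one <- function(y, x, g, X_other) {
    X <- cbind(1, x, g, x * g, X_other)
    XtX <- crossprod(X)
    R <- tryCatch(chol(XtX), error = function(e) NULL)
    if (is.null(R)) return(c(NA_real_, NA_real_, NA_real_, NA_real_))
    b <- backsolve(R, forwardsolve(t(R), crossprod(X, y)))
    res <- y - X %*% b
    df <- length(y) - ncol(X)
    s2 <- sum(res^2) / df
    inv44 <- chol2inv(R)[4, 4]
    se <- sqrt(inv44 * s2)
    c(b[4], se, df, 2 * pt(-abs(b[4] / se), df))
  }
  res <- matrix(NA_real_, length(probes), 4)
  for (i in seq_along(probes)) {
    res[i, ] <- fit_one(beta_blood[probes[i], ], beta_sperm[probes[i], ], g, X_other)
  }
  out <- tibble::tibble(
    probe_id = probes,
    effect = res[, 1],
    se = res[, 2],
    statistic = res[, 1] / res[, 2],
    df = res[, 3],
    p.value = res[, 4],
    significant = !is.na(res[, 4]) & res[, 4] < alpha,
    loo_max_t_change = NA_real_,
    model = "interaction_ols"
  )
  if (loo_diagnostic && any(out$significant)) {
    for (i in which(out$significant)) {
      pr <- out$probe_id[i]
      t_full <- out$statistic[i]
      t_drop <- vapply(seq_len(n), function(j) {
        f <- fit_one(beta_blood[pr, -j], beta_sperm[pr, -j], g[-j],
                     X_other[-j, , drop = FALSE])
        f[1] / f[2]
      }, numeric(1))
      out$loo_max_t_change[i] <- max(abs(t_drop - t_full), na.rm = TRUE)
    }
  }
  new_crossmeth_result(out, "ewas_result", alpha = alpha)
}

#' Enrichment of previously reported probes in a new scan
#'
#' Tests whether probes from a prior study rank lower in p-value than the
#' remaining probes (two-sided Wilcoxon rank-sum test on the p-values), the
#' standard look-up replication check against a published EWAS.
#'
#' @param results Tibble with `probe_id` and `p.value` (an `ewas_result`).
#' @param prior_set Character vector of previously reported probe IDs.
#' @return Tibble: `n_prior` (prior probes present), `n_other`, `p.value`.
#' @export
prior_probe_enrichment <- function(results, prior_set) {
  in_prior <- results$probe_id %in% prior_set
  if (!any(in_prior)) stop("no prior probes present in the results", call. = FALSE)
  wt <- wilcox.test(results$p.value[in_prior], results$p.value[!in_prior])
  tibble::tibble(n_prior = sum(in_prior), n_other = sum(!in_prior),
                 p.value = wt$p.value)
}

#' Concordance of effect sizes with a prior study
#'
#' Spearman rank correlation between locally estimated effects and published
#' effects over the shared probes (rank-based, to allow for study-specific
#' scale biases).
#'
#' @param effects_local Tibble with `probe_id`, `effect`.
#' @param effects_prior Tibble with `probe_id`, `effect`.
#' @return Tibble: `rho`, `p.value`, `n`.
#' @export
effect_concordance <- function(effects_local, effects_prior) {
  shared <- intersect(effects_local$probe_id, effects_prior$probe_id)
  if (length(shared) < 3) stop("fewer than 3 shared probes", call. = FALSE)
  a <- effects_local$effect[match(shared, effects_local$probe_id)]
  b <- effects_prior$effect[match(shared, effects_prior$probe_id)]
  ct <- suppressWarnings(cor.test(a, b, method = "spearman"))
  tibble::tibble(rho = unname(ct$estimate), p.value = ct$p.value, n = length(shared))
}
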