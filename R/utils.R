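# Internal numerical helpers shared across modules.

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' @noRd
assert_beta_matrix <- function(beta, arg = "beta") {
  if (!is.matrix(beta) || !is.numeric(beta)) {
    stop("`", arg, "` must be a numeric probe x sample matrix", call. = FALSE)
  }
  if (is.null(rownames(beta))) {
    stop("`", arg, "` must carry probe identifiers as rownames", call. = FALSE)
  }
  invisible(beta)
}

# Align two beta matrices on shared probes and on paired samples.
# `pairing` is a tibble/data.frame with columns blood, sperm naming columns of
# the respective matrices; NULL pairs columns positionally by shared names.
align_pair <- function(beta_blood, beta_sperm, pairing = NULL) {
  assert_beta_matrix(beta_blood, "beta_blood")
  assert_beta_matrix(beta_sperm, "beta_sperm")
  probes <- intersect(rownames(beta_blood), rownames(beta_sperm))
  if (length(probes) == 0L) stop("no shared probes between tissues", call. = FALSE)
  if (is.null(pairing)) {
    shared <- intersect(colnames(beta_blood), colnames(beta_sperm))
    if (length(shared) == 0L) stop("no shared sample identifiers; supply `pairing`", call. = FALSE)
    pairing <- tibble::tibble(blood = shared, sperm = shared)
  }
  missing_b <- setdiff(pairing$blood, colnames(beta_blood))
  missing_s <- setdiff(pairing$sperm, colnames(beta_sperm))
  if (length(missing_b) || length(missing_s)) {
    stop("pairing references samples absent from the matrices: ",
         paste(c(missing_b, missing_s), collapse = ", "), call. = FALSE)
  }
  list(
    blood = beta_blood[probes, pairing$blood, drop = FALSE],
    sperm = beta_sperm[probes, pairing$sperm, drop = FALSE],
    probes = probes,
    pairing = pairing
  )
}

# Row-wise Pearson correlation between two aligned matrices (same dim).
# Returns r with NA where either row is constant.
row_cor <- function(x, y) {
  xc <- x - rowMeans(x)
  yc <- y - rowMeans(y)
  sxx <- rowSums(xc^2)
  syy <- rowSums(yc^2)
  sxy <- rowSums(xc * yc)
  r <- sxy / sqrt(sxx * syy)
  r[sxx <= 0 | syy <= 0] <- NA_real_
  r
}

# Two-sided p for Pearson r via the t transform on n - 2 df.
cor_pvalue <- function(r, n) {
  df <- n - 2
  tstat <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  2 * pt(-abs(tstat), df)
}

# Generalized extreme studentized deviate (Rosner) test.
# Returns indices of values declared outliers at `alpha` testing up to `k_max`.
esd_outliers <- function(x, k_max, alpha = 0.05) {
  n <- length(x)
  if (n < 4L || k_max < 1L) return(integer(0))
  k_max <- min(k_max, n - 2L)
  idx_left <- seq_len(n)
  removed <- integer(k_max)
  stat_ok <- logical(k_max)
  xs <- x
  for (i in seq_len(k_max)) {
    m <- mean(xs)
    s <- sd(xs)
    if (!is.finite(s) || s == 0) break
    dev <- abs(xs - m)
    j <- which.max(dev)
    Ri <- dev[j] / s
    ni <- length(xs)
    p <- 1 - alpha / (2 * ni)
    tcrit <- qt(p, ni - 2)
    lambda <- (ni - 1) * tcrit / sqrt((ni - 2 + tcrit^2) * ni)
    removed[i] <- idx_left[j]
    stat_ok[i] <- Ri > lambda
    idx_left <- idx_left[-j]
    xs <- xs[-j]
  }
  n_out <- 0L
  for (i in rev(seq_len(k_max))) if (isTRUE(stat_ok[i])) { n_out <- i; break }
  removed[seq_len(n_out)]
}

# Per-coefficient OLS over many probes sharing one design matrix.
# Y: n_obs x n_probes response matrix; X: n_obs x p design; term: column of X.
# Returns tibble(estimate, se, statistic, df, p.value) per probe.
ols_scan <- function(X, Y, term) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    cn <- colnames(X)
    drop_cols <- cn[qrX$pivot[seq.int(qrX$rank + 1L, ncol(X))]]
    stop("design matrix is collinear; offending columns: ",
         paste(drop_cols, collapse = ", "), call. = FALSE)
  }
  n <- nrow(X); p <- ncol(X)
  B <- qr.coef(qrX, Y)
  res <- Y - X %*% B
  s2 <- colSums(res^2) / (n - p)
  XtXinv <- chol2inv(qr.R(qrX))
  j <- if (is.character(term)) match(term, colnames(X)) else term
  if (is.na(j)) stop("term `", term, "` not found in design", call. = FALSE)
  se <- sqrt(XtXinv[j, j] * s2)
  est <- B[j, ]
  tstat <- est / se
  tibble::tibble(
    estimate = unname(est),
    se = unname(se),
    statistic = unname(tstat),
    df = n - p,
    p.value = unname(2 * pt(-abs(tstat), n - p))
  )
}

new_crossmeth_result <- function(x, class, ...) {
  structure(x, class = c(class, class(x)), ...)
}
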