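#' Site-wise paired t-test of sperm versus blood methylation
#'
#' For every probe, tests the paired difference (sperm minus blood; positive
#' effect = sperm hypermethylated) across matched individuals with a Student
#' t-test on `n_pairs - 1` degrees of freedom. Pairs with a missing value at a
#' probe are dropped for that probe (pairwise-complete); probes with fewer
#' than 4 complete pairs are reported with `p = NA` and excluded from
#' significance counts.
#'
#' @param beta_blood,beta_sperm Probe x sample beta matrices.
#' @param pairing Tibble with columns `blood` and `sperm` naming paired sample
#'   columns; `NULL` pairs shared column names.
#' @param alpha Significance threshold; default `9e-8`, the array-wide
#'   threshold recommended for EPIC-scale scans.
#' @return Tibble of class `paired_test_result`: `probe_id`, `effect` (mean
#'   paired difference on the beta scale), `statistic`, `df`, `p.value`,
#'   `n_pairs`, `significant`.
#' @export
sitewise_paired_test <- function(beta_blood, beta_sperm, pairing = NULL,
                                 alpha = 9e-8) {
  al <- align_pair(beta_blood, beta_sperm, pairing)
  d <- al$sperm - al$blood
  n_pairs <- rowSums(!is.na(d))
  m <- rowMeans(d, na.rm = TRUE)
  s <- matrixStats::rowSds(d, na.rm = TRUE)
  tstat <- ifelse(s == 0, ifelse(m == 0, 0, sign(m) * Inf),
                  m / (s / sqrt(n_pairs)))
  df <- n_pairs - 1
  p <- 2 * pt(-abs(tstat), df)
  too_few <- n_pairs < 4
  p[too_few] <- NA_real_
  res <- tibble::tibble(
    probe_id = al$probes,
    effect = unname(m),
    statistic = unname(tstat),
    df = unname(df),
    p.value = unname(p),
    n_pairs = unname(n_pairs),
    significant = unname(!is.na(p) & p < alpha)
  )
  new_crossmeth_result(res, "paired_test_result", alpha = alpha)
}

#' Region-wise paired test of median methylation
#'
#' For each region class the pairing unit is the probe: its cross-sample
#' median in sperm versus its cross-sample median in blood, compared with a
#' paired t-test across all probes annotated to the region. The effect is the
#' mean of (sperm median - blood median).
#'
#' @param beta_blood,beta_sperm Probe x sample beta matrices sharing probes.
#' @param annotation Tibble with `probe_id` and the column named by
#'   `region_col`.
#' @param region_col Annotation column defining region classes.
#' @param alpha Significance threshold (default 0.05 for the handful of
#'   region-level tests).
#' @return Tibble: `region`, `effect`, `statistic`, `df`, `p.value`,
#'   `n_probes`, `significant`. Regions with fewer than 4 probes get `NA`
#'   with a warning.
#' @export
regionwise_paired_test <- function(beta_blood, beta_sperm, annotation,
                                   region_col = "cpg_region", alpha = 0.05) {
  al <- align_pair(beta_blood, beta_sperm,
                   tibble::tibble(blood = colnames(beta_blood),
                                  sperm = colnames(beta_sperm)))
  med_b <- matrixStats::rowMedians(al$blood)
  med_s <- matrixStats::rowMedians(al$sperm)
  names(med_b) <- names(med_s) <- al$probes
  ann <- annotation[annotation$probe_id %in% al$probes, ]
  regions <- unique(ann[[region_col]])
  out <- purrr::map(regions, function(rg) {
    ids <- ann$probe_id[ann[[region_col]] == rg]
    if (length(ids) < 4) {
      warning("region `", rg, "` has fewer than 4 probes; NA returned")
      return(tibble::tibble(region = rg, effect = NA_real_,
                            statistic = NA_real_, df = NA_real_,
                            p.value = NA_real_, n_probes = length(ids),
                            significant = NA))
    }
    d <- med_s[ids] - med_b[ids]
    if (sd(d) < 1e-12) {
      return(tibble::tibble(region = rg, effect = mean(d),
                            statistic = if (mean(d) == 0) 0 else Inf,
                            df = length(d) - 1,
                            p.value = if (mean(d) == 0) 1 else 0,
                            n_probes = length(ids),
                            significant = mean(d) != 0))
    }
    tt <- t.test(d)
    tibble::tibble(region = rg, effect = mean(d),
                   statistic = unname(tt$statistic), df = unname(tt$parameter),
                   p.value = tt$p.value, n_probes = length(ids),
                   significant = tt$p.value < alpha)
  })
  dplyr::bind_rows(out)
}

#' Concordance of effect sizes between cohorts
#'
#' Pearson correlation of per-probe effects between a discovery and a
#' replication cohort, over (optionally) a significant-probe subset.
#'
#' @param effects_a,effects_b Tibbles with `probe_id` and `effect` columns
#'   (e.g. from [sitewise_paired_test()]), or named numeric vectors.
#' @param subset Optional character vector of probe IDs to restrict to.
#' @return Tibble: `r`, `p.value`, `n`.
#' @export
replication_concordance <- function(effects_a, effects_b, subset = NULL) {
  as_vec <- function(x) {
    if (is.data.frame(x)) setNames(x$effect, x$probe_id) else x
  }
  a <- as_vec(effects_a)
  b <- as_vec(effects_b)
  ids <- intersect(names(a), names(b))
  if (!is.null(subset)) ids <- intersect(ids, subset)
  if (length(ids) < 3) stop("fewer than 3 shared probes in the subset", call. = FALSE)
  ct <- cor.test(a[ids], b[ids], method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p.value = ct$p.value, n = length(ids))
}
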