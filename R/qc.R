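#' Quality-control thresholds for probe filtering
#'
#' @param detp_cutoff Detection p-value above which a probe-sample cell counts
#'   as failed (default 0.05).
#' @param detp_sample_fraction A probe is removed when more than this fraction
#'   of samples fail the detection-p cutoff (default 0.05).
#' @param beadcount_min Minimum bead count for a cell to pass (default 3;
#'   cells with fewer beads count as failed).
#' @param beadcount_sample_fraction A probe is removed when at least this
#'   fraction of samples have bead count below `beadcount_min` (default 0.05,
#'   mirroring the detection-p convention).
#' @param snp_proximity_bp Distance (bp) within which a SNP next to the CpG
#'   disqualifies a probe; exclusion lists are expected to encode this rule
#'   (default 10).
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(detp_cutoff = 0.05,
                          detp_sample_fraction = 0.05,
                          beadcount_min = 3,
                          beadcount_sample_fraction = 0.05,
                          snp_proximity_bp = 10) {
  stopifnot(detp_sample_fraction >= 0, detp_sample_fraction <= 1,
            beadcount_sample_fraction >= 0, beadcount_sample_fraction <= 1,
            beadcount_min >= 1)
  structure(list(
    detp_cutoff = detp_cutoff,
    detp_sample_fraction = detp_sample_fraction,
    beadcount_min = beadcount_min,
    beadcount_sample_fraction = beadcount_sample_fraction,
    snp_proximity_bp = snp_proximity_bp
  ), class = "qc_thresholds")
}

#' Filter probes on detection p-value, bead count and exclusion lists
#'
#' Filters are applied in the fixed order detection-p, then bead count, then
#' exclusion lists, and the report itemises the number of probes each stage
#' removed from what the previous stages left. A probe is removed iff it fails
#' at least one filter, so the retained set does not depend on the order; only
#' the per-stage attribution does.
#'
#' @param beta Probe x sample beta matrix.
#' @param detp Optional detection p-value matrix of identical shape; when
#'   `NULL` the detection-p filter is skipped with a warning.
#' @param beads Optional bead-count matrix of identical shape; when `NULL` the
#'   bead filter is skipped with a warning.
#' @param exclusion_lists Named list of character vectors of probe IDs to drop
#'   (e.g. SNP-proximal and cross-reactive probe lists).
#' @param thresholds A [qc_thresholds()] object.
#' @return List with `beta` (the filtered matrix) and `report`, a `qc_report`
#'   containing per-filter removal counts (`filter`, `n_removed` tibble in
#'   application order), the retained probe IDs, and the thresholds used.
#' @export
filter_probes <- function(beta, detp = NULL, beads = NULL,
                          exclusion_lists = list(),
                          thresholds = qc_thresholds()) {
  assert_beta_matrix(beta)
  check_shape <- function(x, nm) {
    if (!identical(dim(x), dim(beta)) ||
        !identical(rownames(x), rownames(beta)) ||
        !identical(colnames(x), colnames(beta))) {
      stop("`", nm, "` must share shape and dimnames with `beta`", call. = FALSE)
    }
  }
  n <- ncol(beta)
  keep <- rep(TRUE, nrow(beta))
  names(keep) <- rownames(beta)
  steps <- list()

  if (is.null(detp)) {
    warning("no detection-p matrix supplied; skipping detection-p filter")
  } else {
    check_shape(detp, "detp")
    frac_fail <- rowMeans(detp > thresholds$detp_cutoff)
    fail <- frac_fail > thresholds$detp_sample_fraction
    steps$detection_p <- sum(fail & keep)
    keep <- keep & !fail
  }
  if (is.null(beads)) {
    warning("no bead-count matrix supplied; skipping bead-count filter")
  } else {
    check_shape(beads, "beads")
    frac_low <- rowMeans(beads < thresholds$beadcount_min)
    fail <- frac_low >= thresholds$beadcount_sample_fraction
    steps$bead_count <- sum(fail & keep)
    keep <- keep & !fail
  }
  if (length(exclusion_lists)) {
    if (is.null(names(exclusion_lists))) {
      names(exclusion_lists) <- paste0("exclusion_", seq_along(exclusion_lists))
    }
    for (nm in names(exclusion_lists)) {
      fail <- rownames(beta) %in% exclusion_lists[[nm]]
      steps[[nm]] <- sum(fail & keep)
      keep <- keep & !fail
    }
  }
  report <- structure(list(
    n_input = nrow(beta),
    n_retained = sum(keep),
    removed = tibble::tibble(
      filter = names(steps),
      n_removed = unname(unlist(steps, use.names = FALSE))
    ),
    retained_probes = rownames(beta)[keep],
    thresholds = unclass(thresholds),
    filter_order = names(steps)
  ), class = "qc_report")
  list(beta = beta[keep, , drop = FALSE], report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Probe QC report:", x$n_input, "probes in,", x$n_retained, "retained\n")
  if (nrow(x$removed)) {
    for (i in seq_len(nrow(x$removed))) {
      cat("  -", x$removed$filter[i], ":", x$removed$n_removed[i], "removed\n")
    }
  }
  invisible(x)
}

#' Flag outlying samples from principal-component scores
#'
#' Projects samples onto principal components of the beta matrix and flags a
#' sample when (rule `pc1_iqr`) its PC1 score lies outside
#' median +/- `iqr_multiplier` x IQR of the PC1 scores, and/or (rule
#' `mad_distance`) its Euclidean distance from the coordinate-wise median of
#' the (PC1, PC2) scores exceeds `mad_multiplier` median absolute deviations.
#' By default both rules must agree for a sample to be flagged.
#'
#' @param beta Probe x sample beta matrix (>= 4 samples).
#' @param iqr_multiplier Width of the PC1 interquartile band (default 2).
#' @param mad_multiplier MAD cutoff for the robust-distance rule (default 5).
#' @param combine `"intersection"` (default; both rules), `"union"`, or the
#'   name of a single rule.
#' @return Tibble with one row per sample: `sample`, `pc1`, `pc2`, per-rule
#'   flags and the combined `outlier` flag.
#' @export
detect_outlier_samples <- function(beta, iqr_multiplier = 2, mad_multiplier = 5,
                                   combine = c("intersection", "union",
                                               "pc1_iqr", "mad_distance")) {
  assert_beta_matrix(beta)
  combine <- match.arg(combine)
  if (ncol(beta) < 4) stop("need at least 4 samples", call. = FALSE)
  X <- t(beta)
  if (all(abs(X - rep(colMeans(X), each = nrow(X))) < .Machine$double.eps^0.5)) {
    warning("constant beta matrix: no principal components; no samples flagged")
    return(tibble::tibble(sample = colnames(beta), pc1 = 0, pc2 = 0,
                          pc1_iqr = FALSE, mad_distance = FALSE, outlier = FALSE))
  }
  pc <- prcomp(X, center = TRUE, scale. = FALSE, rank. = 2)
  s1 <- pc$x[, 1]
  s2 <- if (ncol(pc$x) >= 2) pc$x[, 2] else rep(0, length(s1))
  med <- median(s1)
  iqr <- stats::IQR(s1)
  flag_iqr <- s1 < med - iqr_multiplier * iqr | s1 > med + iqr_multiplier * iqr
  d <- sqrt((s1 - median(s1))^2 + (s2 - median(s2))^2)
  madd <- stats::mad(d)
  flag_mad <- if (madd > 0) d > median(d) + mad_multiplier * madd else rep(FALSE, length(d))
  outlier <- switch(combine,
    intersection = flag_iqr & flag_mad,
    union = flag_iqr | flag_mad,
    pc1_iqr = flag_iqr,
    mad_distance = flag_mad
  )
  tibble::tibble(sample = colnames(beta), pc1 = unname(s1), pc2 = unname(s2),
                 pc1_iqr = unname(flag_iqr), mad_distance = unname(flag_mad),
                 outlier = unname(outlier))
}

#' Probe-type-stratified between-sample quantile normalization
#'
#' Harmonises beta distributions between samples separately within each probe
#' chemistry stratum (Infinium type I and type II), so that within a stratum
#' every sample ends up with the identical sorted-value profile while ranks
#' within each sample are preserved. This is a beta-scale re-specification of
#' intensity-based type-stratified normalization.
#'
#' @param beta Probe x sample beta matrix.
#' @param probe_type Character vector (`"I"`/`"II"`) of length `nrow(beta)`,
#'   or a tibble with `probe_id` and `probe_type` columns covering all probes.
#' @return Normalized beta matrix, same shape, values in `[0, 1]`.
#' @export
normalize_betas <- function(beta, probe_type) {
  assert_beta_matrix(beta)
  if (is.data.frame(probe_type)) {
    idx <- match(rownames(beta), probe_type$probe_id)
    if (anyNA(idx)) stop("probe types missing for some probes", call. = FALSE)
    probe_type <- probe_type$probe_type[idx]
  }
  if (length(probe_type) != nrow(beta)) {
    stop("`probe_type` must give one label per probe", call. = FALSE)
  }
  bad <- !probe_type %in% c("I", "II")
  if (any(bad)) {
    stop("unknown probe type label(s): ",
         paste(unique(probe_type[bad]), collapse = ", "), call. = FALSE)
  }
  out <- beta
  for (tp in unique(probe_type)) {
    rows <- probe_type == tp
    out[rows, ] <- limma::normalizeQuantiles(beta[rows, , drop = FALSE])
  }
  clip01(out)
}

#' Check genotype concordance between paired samples at SNP probes
#'
#' The non-CpG SNP probes on the array read out genotype, not methylation;
#' matched samples from the same individual must agree there. A pair is
#' concordant iff the Pearson correlation of its SNP-probe betas is at least
#' `r_min`; a constant SNP vector in either tissue makes the correlation
#' undefined and yields the verdict `"indeterminate"`.
#'
#' @param beta_blood,beta_sperm Beta matrices restricted to SNP probes
#'   (>= 5 shared probes).
#' @param pairing Tibble with columns `blood` and `sperm` naming the paired
#'   sample columns; `NULL` pairs shared column names.
#' @param r_min Concordance threshold (default 0.9).
#' @return Tibble with `blood`, `sperm`, `r`, `n_probes`, `verdict`
#'   (`"concordant"`, `"discordant"`, `"indeterminate"`).
#' @export
check_genotype_concordance <- function(beta_blood, beta_sperm, pairing = NULL,
                                       r_min = 0.9) {
  al <- align_pair(beta_blood, beta_sperm, pairing)
  if (length(al$probes) < 5) stop("need at least 5 shared SNP probes", call. = FALSE)
  r <- vapply(seq_len(nrow(al$pairing)), function(i) {
    x <- al$blood[, i]; y <- al$sperm[, i]
    if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
    cor(x, y)
  }, numeric(1))
  tibble::tibble(
    blood = al$pairing$blood,
    sperm = al$pairing$sperm,
    r = r,
    n_probes = length(al$probes),
    verdict = dplyr::case_when(
      is.na(r) ~ "indeterminate",
      r >= r_min ~ "concordant",
      TRUE ~ "discordant"
    )
  )
}
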