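#' Select variable sites across both tissues
#'
#' A probe is kept iff the methylation range spanned by the middle
#' `inner_fraction` of samples (default: the 10th-90th percentile range) is at
#' least `min_range` in BOTH tissues. Restricting correlation scans to such
#' sites avoids correlations manufactured by single outliers at otherwise
#' invariant probes. Quantiles use linear interpolation (type 7); the boundary
#' is inclusive (`>=`).
#'
#' @param beta_blood,beta_sperm Probe x sample beta matrices sharing probes.
#' @param inner_fraction Central fraction of samples defining the range
#'   (default 0.80).
#' @param min_range Minimum beta range (default 0.05, i.e. 5% methylation).
#' @return Character vector of retained probe IDs.
#' @export
select_variable_sites <- function(beta_blood, beta_sperm,
                                  inner_fraction = 0.80, min_range = 0.05) {
  stopifnot(inner_fraction > 0, inner_fraction <= 1, min_range > 0)
  al <- align_pair(beta_blood, beta_sperm,
                   tibble::tibble(blood = colnames(beta_blood),
                                  sperm = colnames(beta_sperm)))
  lo <- (1 - inner_fraction) / 2
  probs <- c(lo, 1 - lo)
  rng <- function(m) {
    q <- matrixStats::rowQuantiles(m, probs = probs, type = 7L)
    q[, 2] - q[, 1]
  }
  keep <- rng(al$blood) >= min_range & rng(al$sperm) >= min_range
  al$probes[keep]
}

#' Per-site cross-tissue Pearson correlation
#'
#' Correlates blood and sperm methylation across matched individuals at each
#' probe; two-sided p-values come from the t transform of r on `n - 2`
#' degrees of freedom. Probes with zero variance in either tissue get
#' `r = NA`.
#'
#' @param beta_blood,beta_sperm Probe x sample beta matrices.
#' @param pairing Tibble with `blood`/`sperm` columns naming paired samples;
#'   `NULL` pairs shared column names.
#' @param alpha Significance threshold (default `9e-8`).
#' @return Tibble of class `correlation_result`: `probe_id`, `r`, `p.value`,
#'   `n_pairs`, `significant`, `negative` (`r < 0`).
#' @export
correlate_sites <- function(beta_blood, beta_sperm, pairing = NULL,
                            alpha = 9e-8) {
  al <- align_pair(beta_blood, beta_sperm, pairing)
  n <- nrow(al$pairing)
  if (n < 4) stop("need at least 4 complete pairs", call. = FALSE)
  r <- row_cor(al$blood, al$sperm)
  p <- cor_pvalue(r, n)
  res <- tibble::tibble(
    probe_id = al$probes,
    r = unname(r),
    p.value = unname(p),
    n_pairs = n,
    significant = !is.na(p) & p < alpha,
    negative = !is.na(r) & r < 0
  )
  new_crossmeth_result(res, "correlation_result", alpha = alpha)
}

#' Permutation null distribution for cross-tissue correlations
#'
#' Breaks the individual pairing by permuting which sperm sample is matched to
#' which blood sample (a uniform random permutation of sperm labels per
#' permutation round) and recomputes the per-site correlations, pooling r
#' across permutations and probes. The pooled distribution is the null against
#' which the observed correlation histogram is compared.
#'
#' @param beta_blood,beta_sperm Probe x sample beta matrices.
#' @param variable_probes Optional probe subset (e.g. from
#'   [select_variable_sites()]); `NULL` uses all shared probes.
#' @param n_perm Number of permutations (>= 0; 0 returns an empty
#'   distribution).
#' @param seed Integer seed; identical seeds give identical output.
#' @return Object of class `perm_null`: list with `r` (pooled null
#'   correlations), `n_perm`, `n_pairs`, `n_probes`, and `quantiles` (an
#'   empirical-quantile summary of the pooled null).
#' @export
permutation_null <- function(beta_blood, beta_sperm, variable_probes = NULL,
                             n_perm = 100, seed = 1L) {
  al <- align_pair(beta_blood, beta_sperm)
  if (!is.null(variable_probes)) {
    keep <- al$probes %in% variable_probes
    al$blood <- al$blood[keep, , drop = FALSE]
    al$sperm <- al$sperm[keep, , drop = FALSE]
    al$probes <- al$probes[keep]
  }
  n <- ncol(al$blood)
  set.seed(seed)
  rs <- vector("list", n_perm)
  for (i in seq_len(n_perm)) {
    perm <- sample.int(n)
    rs[[i]] <- row_cor(al$blood, al$sperm[, perm, drop = FALSE])
  }
  r <- unlist(rs, use.names = FALSE)
  r <- r[!is.na(r)]
  qs <- if (length(r)) {
    quantile(r, c(0.005, 0.025, 0.25, 0.5, 0.75, 0.975, 0.995))
  } else {
    setNames(rep(NA_real_, 7),
             c("0.5%", "2.5%", "25%", "50%", "75%", "97.5%", "99.5%"))
  }
  structure(list(r = r, n_perm = n_perm, n_pairs = n,
                 n_probes = length(al$probes), quantiles = qs, seed = seed),
            class = "perm_null")
}

#' @export
print.perm_null <- function(x, ...) {
  cat("Permutation null:", x$n_perm, "permutations x", x$n_probes,
      "probes (", length(x$r), "pooled r values )\n")
  if (length(x$r)) print(round(x$quantiles, 4))
  invisible(x)
}

#' Configuration for modality classification
#'
#' @param gap_cutoff Minimum gap between consecutive sorted beta values that
#'   splits groups in [gap_hunt()] (default 0.05, i.e. 5% methylation).
#' @param variance_ratio_min Minimum between-cluster to within-cluster
#'   sum-of-squares ratio for a clustering to stand; below it the cluster
#'   count is decremented (default 2).
#' @param outlier_fraction_max A solution's smallest group marks the site
#'   outlier-driven when its size is at most `max(1, outlier_fraction_max * n)`
#'   (default 0.05).
#' @param esd_max_outliers Maximum outliers tested by the generalized-ESD
#'   screen; `NULL` means `ceiling(0.1 * n)`.
#' @param esd_alpha Significance level of the ESD screen (default 0.05).
#' @param candidate_k Candidate cluster numbers (default `c(2, 3)`).
#' @param algorithm `"pam"` (k-medoids, default, robust) or `"kmeans"`.
#' @return A `modality_config` list.
#' @export
modality_config <- function(gap_cutoff = 0.05, variance_ratio_min = 2,
                            outlier_fraction_max = 0.05,
                            esd_max_outliers = NULL, esd_alpha = 0.05,
                            candidate_k = c(2L, 3L),
                            algorithm = c("pam", "kmeans")) {
  stopifnot(gap_cutoff > 0, variance_ratio_min > 0)
  structure(list(
    gap_cutoff = gap_cutoff,
    variance_ratio_min = variance_ratio_min,
    outlier_fraction_max = outlier_fraction_max,
    esd_max_outliers = esd_max_outliers,
    esd_alpha = esd_alpha,
    candidate_k = as.integer(candidate_k),
    algorithm = match.arg(algorithm)
  ), class = "modality_config")
}

.modality_labels <- c("unimodal", "bimodal", "trimodal")

cluster_ss_ratio <- function(points, cl) {
  centers <- rowsum(points, cl) / as.vector(table(cl))
  grand <- colMeans(points)
  within <- sum((points - centers[as.character(cl), , drop = FALSE])^2)
  between <- sum(as.vector(table(cl)) *
                   rowSums(sweep(centers, 2, grand)^2))
  if (within <= .Machine$double.eps) return(Inf)
  between / within
}

cluster_points <- function(points, k, algorithm) {
  if (algorithm == "pam") {
    fit <- cluster::pam(points, k, keep.diss = FALSE, keep.data = FALSE)
    list(cl = fit$clustering, sil = fit$silinfo$avg.width)
  } else {
    fit <- stats::kmeans(points, k, nstart = 5)
    sil <- cluster::silhouette(fit$cluster, stats::dist(points))
    list(cl = fit$cluster, sil = mean(sil[, 3]))
  }
}

#' Classify cross-tissue modality by outlier-screened clustering
#'
#' Two-dimensional modality call for one probe's paired (blood, sperm) beta
#' values. A generalized-ESD (Rosner) screen on Euclidean distances from the
#' coordinate-wise median flags apparent outliers; k-medoids (or k-means)
#' clustering at the candidate cluster numbers is then scored by average
#' silhouette width, and a winning solution whose between- to within-cluster
#' sum-of-squares ratio falls below `variance_ratio_min` has its cluster count
#' decremented (2 clusters decrement to a unimodal call). A multi-cluster call
#' is flagged outlier-driven when its smallest cluster holds at most
#' `max(1, outlier_fraction_max * n)` points or when every minority cluster
#' consists solely of ESD-flagged points.
#'
#' @param blood,sperm Numeric vectors of paired beta values (same length,
#'   n >= 8), or `blood` may be an n x 2 matrix.
#' @param config A [modality_config()].
#' @return Tibble row: `modality` (`unimodal`/`bimodal`/`trimodal` or
#'   `indeterminate` for n < 8), `n_clusters`, `outlier_driven`,
#'   `n_esd_outliers`, `silhouette`, `variance_ratio`, and `clusters`
#'   (list-column with the per-point assignment).
#' @export
classify_modality_kmeans <- function(blood, sperm = NULL,
                                     config = modality_config()) {
  points <- if (is.matrix(blood)) blood else cbind(blood, sperm)
  colnames(points) <- c("blood", "sperm")
  n <- nrow(points)
  empty <- function(modality) tibble::tibble(
    modality = modality, n_clusters = NA_integer_, outlier_driven = NA,
    n_esd_outliers = NA_integer_, silhouette = NA_real_,
    variance_ratio = NA_real_, clusters = list(rep(NA_integer_, n))
  )
  if (n < 8) return(empty("indeterminate"))

  ctr <- apply(points, 2, median)
  d <- sqrt(rowSums(sweep(points, 2, ctr)^2))
  k_max <- config$esd_max_outliers %||% ceiling(0.1 * n)
  esd_idx <- esd_outliers(d, k_max = k_max, alpha = config$esd_alpha)

  fits <- lapply(config$candidate_k, function(k) {
    if (k >= n) return(NULL)
    c(cluster_points(points, k, config$algorithm), list(k = k))
  })
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) return(empty("unimodal"))
  sils <- vapply(fits, function(f) f$sil, numeric(1))
  best <- fits[[which.max(sils)]]
  k <- best$k
  cl <- best$cl
  ratio <- cluster_ss_ratio(points, cl)
  # decrement rule: a weakly separated solution drops one cluster at a time
  while (k >= 2 && ratio < config$variance_ratio_min) {
    k <- k - 1L
    if (k == 1L) break
    refit <- cluster_points(points, k, config$algorithm)
    cl <- refit$cl
    ratio <- cluster_ss_ratio(points, cl)
    best$sil <- refit$sil
  }
  if (k == 1L) {
    return(tibble::tibble(
      modality = "unimodal", n_clusters = 1L, outlier_driven = FALSE,
      n_esd_outliers = length(esd_idx), silhouette = NA_real_,
      variance_ratio = ratio, clusters = list(rep(1L, n))
    ))
  }
  sizes <- as.vector(table(cl))
  smallest <- min(sizes)
  minority <- which(cl != as.integer(names(which.max(table(cl))))[1])
  minority_all_esd <- length(minority) > 0 && all(minority %in% esd_idx)
  outlier_driven <- smallest <= max(1, config$outlier_fraction_max * n) ||
    minority_all_esd
  tibble::tibble(
    modality = .modality_labels[min(k, 3L)],
    n_clusters = as.integer(k),
    outlier_driven = outlier_driven,
    n_esd_outliers = length(esd_idx),
    silhouette = best$sil,
    variance_ratio = ratio,
    clusters = list(as.integer(cl))
  )
}

#' Gap hunting: one-dimensional modality from sorted-value gaps
#'
#' Sorts one tissue's beta values and splits wherever consecutive sorted
#' values differ by more than `gap_cutoff` (default 5% methylation). The group
#' count determines the modality call (three or more groups are reported as
#' trimodal, with the count retained); a site is outlier-driven when any group
#' holds at most `max(1, outlier_fraction_max * n)` values.
#'
#' @param values Numeric vector of beta values from one tissue (n >= 2).
#' @param config A [modality_config()].
#' @return Tibble row: `modality`, `n_groups`, `outlier_driven`, `groups`
#'   (list-column with per-value group assignment, in input order).
#' @export
gap_hunt <- function(values, config = modality_config()) {
  n <- length(values)
  if (n < 2) stop("need at least 2 values", call. = FALSE)
  ord <- order(values)
  sorted <- values[ord]
  new_group <- c(FALSE, diff(sorted) > config$gap_cutoff)
  grp_sorted <- cumsum(new_group) + 1L
  groups <- integer(n)
  groups[ord] <- grp_sorted
  n_groups <- max(grp_sorted)
  sizes <- tabulate(grp_sorted)
  outlier_driven <- n_groups > 1L && any(sizes <= max(1, config$outlier_fraction_max * n))
  tibble::tibble(
    modality = .modality_labels[min(n_groups, 3L)],
    n_groups = n_groups,
    outlier_driven = outlier_driven,
    groups = list(groups)
  )
}

#' Dual modality classification of correlated sites
#'
#' Runs both modality methods over a set of (typically significantly
#' correlated) probes: the two-dimensional outlier-screened clustering call
#' and per-tissue gap hunting.
#'
#' @param beta_blood,beta_sperm Probe x sample beta matrices.
#' @param probes Probe IDs to classify (e.g. significant probes from
#'   [correlate_sites()]).
#' @param config A [modality_config()].
#' @return Tibble with one row per probe: `probe_id`, `modality_kmeans`,
#'   `outlier_driven_kmeans`, `modality_gap_blood`, `outlier_driven_gap_blood`,
#'   `modality_gap_sperm`, `outlier_driven_gap_sperm`.
#' @export
classify_correlated_sites <- function(beta_blood, beta_sperm, probes,
                                      config = modality_config()) {
  al <- align_pair(beta_blood, beta_sperm)
  probes <- intersect(probes, al$probes)
  purrr::map(probes, function(p) {
    b <- al$blood[p, ]
    s <- al$sperm[p, ]
    km <- classify_modality_kmeans(b, s, config)
    gb <- gap_hunt(b, config)
    gs <- gap_hunt(s, config)
    tibble::tibble(
      probe_id = p,
      modality_kmeans = km$modality,
      outlier_driven_kmeans = km$outlier_driven,
      modality_gap_blood = gb$modality,
      outlier_driven_gap_blood = gb$outlier_driven,
      modality_gap_sperm = gs$modality,
      outlier_driven_gap_sperm = gs$outlier_driven
    )
  }) |> dplyr::bind_rows()
}

#' Nearest-SNP distance and position category per probe
#'
#' For each probe, takes the offsets (bp from the interrogated CpG) of known
#' SNPs in the probe sequence and reports the distance to the nearest SNP and
#' a position category. Type II probes interrogate the CpG dinucleotide at
#' offsets 0/1 (which also covers their extension base), so a distance of at
#' most 1 is `cpg_site`; type I probes read the CpG at offset 0 and extend at
#' offset -1 (`single_base_extension`). Everything else inside the probe
#' footprint is `probe_body`; probes without SNPs get `none` and an infinite
#' distance.
#'
#' @param annotation Tibble with `probe_id`, `probe_type` and `snp_offsets`
#'   (list-column of integer offsets; `NULL`/empty = no known SNP).
#' @param probes Optional probe subset.
#' @param footprint Probe footprint half-width in bp (offsets must satisfy
#'   `|offset| <= footprint`; default 50).
#' @return Tibble: `probe_id`, `probe_type`, `snp_distance`, `snp_category`.
#' @export
annotate_snps <- function(annotation, probes = NULL, footprint = 50) {
  ann <- annotation
  if (!is.null(probes)) ann <- ann[ann$probe_id %in% probes, ]
  purrr::pmap(
    list(ann$probe_id, ann$probe_type, ann$snp_offsets),
    function(id, type, offs) {
      if (is.null(offs) || length(offs) == 0) {
        return(tibble::tibble(probe_id = id, probe_type = type,
                              snp_distance = Inf, snp_category = "none"))
      }
      offs <- as.integer(offs)
      if (any(abs(offs) > footprint)) {
        stop("SNP offset outside the ", footprint, " bp probe footprint for probe ",
             id, call. = FALSE)
      }
      d <- min(abs(offs))
      category <- if (type == "II") {
        if (d <= 1) "cpg_site" else "probe_body"
      } else {
        if (any(offs == 0L)) "cpg_site"
        else if (any(offs == -1L)) "single_base_extension"
        else "probe_body"
      }
      tibble::tibble(probe_id = id, probe_type = type,
                     snp_distance = d, snp_category = category)
    }
  ) |> dplyr::bind_rows()
}

#' Genetic-annotation enrichment among correlated sites
#'
#' Fisher exact test of a binary genetic annotation (e.g. CorSIV membership or
#' previously reported mQTL status) among significantly correlated probes
#' against the background of non-correlated variable probes. For annotations
#' defined only on a sub-array (e.g. 450K-derived mQTL lists), both sets are
#' first restricted to the probes on which the flag is defined via
#' `restrict_to`.
#'
#' @param correlated Character vector of correlated probe IDs.
#' @param background Character vector of non-correlated variable probe IDs
#'   (must be disjoint from `correlated`).
#' @param flags Character vector of flagged probe IDs.
#' @param restrict_to Optional character vector of probes on which the flag is
#'   defined; both sets are intersected with it first.
#' @param label Region/annotation label for the output row.
#' @return One-row tibble: counts, `odds_ratio`, `p`, `p_report`.
#' @export
genetic_enrichment <- function(correlated, background, flags,
                               restrict_to = NULL, label = "annotation") {
  if (length(intersect(correlated, background))) {
    stop("`correlated` and `background` must be disjoint", call. = FALSE)
  }
  if (!is.null(restrict_to)) {
    correlated <- intersect(correlated, restrict_to)
    background <- intersect(background, restrict_to)
  }
  if (!length(correlated) || !length(background)) {
    stop("empty probe set after restriction", call. = FALSE)
  }
  a <- sum(correlated %in% flags)
  b <- length(correlated) - a
  c_ <- sum(background %in% flags)
  d <- length(background) - c_
  fisher_enrichment(a, b, c_, d, label)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
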