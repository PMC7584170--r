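#' Methylation-category thresholds
#'
#' Sites are classed by their cross-sample median beta: low (`< low_max`),
#' high (`> high_min`), intermediate otherwise (boundaries fall into
#' intermediate). The imprint band is the interval of intermediate methylation
#' characteristic of parent-of-origin allele-specific methylation in somatic
#' tissue (around 50%).
#'
#' @param low_max Upper bound of the low category (default 0.20).
#' @param high_min Lower bound of the high category (default 0.80).
#' @param imprint_band Length-2 numeric interval (default `c(0.40, 0.60)`).
#' @return A `category_thresholds` list.
#' @export
category_thresholds <- function(low_max = 0.20, high_min = 0.80,
                                imprint_band = c(0.40, 0.60)) {
  stopifnot(low_max >= 0, low_max < high_min, high_min <= 1,
            length(imprint_band) == 2,
            imprint_band[1] > low_max, imprint_band[2] < high_min)
  structure(list(low_max = low_max, high_min = high_min,
                 imprint_band = imprint_band),
            class = "category_thresholds")
}

#' Categorize sites by cross-sample median methylation
#'
#' @param beta Probe x sample beta matrix (>= 1 sample).
#' @param thresholds A [category_thresholds()] object.
#' @return Tibble with `probe_id`, `median_beta`, `category`
#'   (`low`/`intermediate`/`high`; exhaustive and mutually exclusive).
#' @export
categorize_sites <- function(beta, thresholds = category_thresholds()) {
  assert_beta_matrix(beta)
  if (ncol(beta) < 1) stop("need at least 1 sample", call. = FALSE)
  med <- matrixStats::rowMedians(beta)  # type-7 interpolation between order stats
  tibble::tibble(
    probe_id = rownames(beta),
    median_beta = med,
    category = dplyr::case_when(
      med < thresholds$low_max ~ "low",
      med > thresholds$high_min ~ "high",
      TRUE ~ "intermediate"
    )
  )
}

# Two-sided Fisher exact test on a 2x2 table given as counts a,b,c,d
# (rows: in-region / not, columns: target / background). Reports the
# conditional-MLE odds ratio convention of stats::fisher.test alongside the
# sample odds ratio; p floored at 1e-50 in `p_report`.
fisher_enrichment <- function(a, b, c, d, label, p_floor = 1e-50) {
  ft <- fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE))
  or <- if (b == 0 || c == 0) {
    if (a == 0 || d == 0) NA_real_ else Inf
  } else {
    (a * d) / (b * c)
  }
  tibble::tibble(
    region = label, a = a, b = b, c = c, d = d,
    odds_ratio = or,
    p = ft$p.value,
    p_report = max(ft$p.value, p_floor)
  )
}

#' Region enrichment of extreme-methylation sites
#'
#' For each region class, tests whether sites of the target methylation
#' category (low or high) are enriched in the region relative to the
#' background of intermediately methylated sites, with a two-sided Fisher
#' exact test on the 2x2 table (in region vs not) x (target vs background).
#' Probes may belong to several region classes. Reported p-values are floored
#' at 1e-50 in `p_report` (raw values kept in `p`).
#'
#' @param categories Tibble from [categorize_sites()].
#' @param annotation Probe annotation tibble with `probe_id` and the column
#'   named by `region_col`.
#' @param target_category `"low"` or `"high"`.
#' @param region_col Annotation column defining region classes (e.g.
#'   `"cpg_region"` or `"genomic_region"`).
#' @param background_category Category forming the background (default
#'   `"intermediate"`).
#' @return Tibble with one row per region: counts `a` (in region, target),
#'   `b` (not in region, target), `c` (in region, background), `d` (not in
#'   region, background), `odds_ratio`, `p`, `p_report`. Regions with zero
#'   probes are omitted with a warning.
#' @export
region_enrichment <- function(categories, annotation,
                              target_category = c("low", "high"),
                              region_col = "cpg_region",
                              background_category = "intermediate") {
  target_category <- match.arg(target_category)
  df <- dplyr::inner_join(categories, annotation, by = "probe_id")
  df <- df[df$category %in% c(target_category, background_category), ]
  regions <- unique(annotation[[region_col]])
  out <- purrr::map(regions, function(rg) {
    inr <- df[[region_col]] == rg
    if (!any(inr)) {
      warning("region `", rg, "` has no probes; omitted")
      return(NULL)
    }
    tg <- df$category == target_category
    fisher_enrichment(sum(inr & tg), sum(!inr & tg),
                      sum(inr & !tg), sum(!inr & !tg), rg)
  })
  dplyr::bind_rows(out)
}

#' Enrichment of imprint-band methylation at imprinted sites
#'
#' For each imprint class and tissue, tests whether sites annotated to the
#' class have cross-sample median methylation inside the imprint band (40-60%
#' by default) more often than the array-wide background, by two-sided Fisher
#' exact test. Blood is expected to show the enrichment (allele-specific
#' methylation averages to ~50%), sperm is not.
#'
#' @param beta_blood,beta_sperm Beta matrices sharing probes.
#' @param imprint_annotation Tibble with `probe_id` and `imprint_class`
#'   (classes other than `"none"` are tested).
#' @param thresholds A [category_thresholds()] object.
#' @return Tibble with one row per (tissue, imprint class): band counts,
#'   odds ratio, `p`, `p_report`. Empty classes are omitted with a warning.
#' @export
imprint_enrichment <- function(beta_blood, beta_sperm, imprint_annotation,
                               thresholds = category_thresholds()) {
  band <- thresholds$imprint_band
  tissues <- list(blood = beta_blood, sperm = beta_sperm)
  out <- purrr::imap(tissues, function(beta, tissue) {
    assert_beta_matrix(beta)
    med <- matrixStats::rowMedians(beta)
    in_band <- med >= band[1] & med <= band[2]
    names(in_band) <- rownames(beta)
    cls_tbl <- imprint_annotation[imprint_annotation$probe_id %in% rownames(beta), ]
    classes <- setdiff(unique(cls_tbl$imprint_class), "none")
    purrr::map(classes, function(cl) {
      ids <- cls_tbl$probe_id[cls_tbl$imprint_class == cl]
      if (!length(ids)) {
        warning("imprint class `", cl, "` is empty; omitted")
        return(NULL)
      }
      is_cl <- names(in_band) %in% ids
      res <- fisher_enrichment(sum(in_band & is_cl), sum(in_band & !is_cl),
                               sum(!in_band & is_cl), sum(!in_band & !is_cl),
                               cl)
      res$tissue <- tissue
      res
    }) |> dplyr::bind_rows()
  })
  dplyr::bind_rows(out) |>
    dplyr::relocate("tissue")
}

#' Overlap probes with genomic intervals
#'
#' Probe positions are 1-based; intervals are 0-based half-open (BED
#' convention): a probe at 1-based position p overlaps `[s, e)` iff
#' `s <= p - 1 < e`.
#'
#' @param annotation Probe annotation tibble with `probe_id`, `chr`,
#'   `position`.
#' @param intervals Tibble/data frame with `chr`, `start`, `end` (0-based
#'   half-open), e.g. from [read_bed()].
#' @return Tibble of probes overlapping at least one interval (`probe_id`,
#'   `chr`, `position`).
#' @export
interval_overlap <- function(annotation, intervals) {
  if (nrow(intervals) == 0) {
    return(annotation[0, c("probe_id", "chr", "position")])
  }
  bad <- intervals$end <= intervals$start
  if (any(bad)) {
    i <- which(bad)[1]
    stop("malformed interval (end <= start): ", intervals$chr[i], ":",
         intervals$start[i], "-", intervals$end[i], call. = FALSE)
  }
  gr_probes <- GenomicRanges::GRanges(
    annotation$chr,
    IRanges::IRanges(start = annotation$position, width = 1)
  )
  # convert 0-based half-open to 1-based closed
  gr_int <- GenomicRanges::GRanges(
    intervals$chr,
    IRanges::IRanges(start = intervals$start + 1L, end = intervals$end)
  )
  hit <- GenomicRanges::countOverlaps(gr_probes, gr_int) > 0
  tibble::as_tibble(annotation[hit, c("probe_id", "chr", "position")])
}

#' Principal-component summary of a combined beta matrix
#'
#' @param beta Probe x sample beta matrix over both tissues (>= 3 samples).
#' @return List of class `pca_summary` with `variance` (tibble: component,
#'   variance fraction, cumulative) and `scores` (tibble: sample, centred
#'   scores per component).
#' @export
pca_summary <- function(beta) {
  assert_beta_matrix(beta)
  if (ncol(beta) < 3) stop("need at least 3 samples", call. = FALSE)
  X <- t(beta)
  if (all(matrixStats::colVars(X) < .Machine$double.eps)) {
    stop("constant beta matrix: principal components undefined", call. = FALSE)
  }
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- tibble::as_tibble(pc$x, rownames = "sample")
  structure(list(
    variance = tibble::tibble(
      component = seq_along(ve),
      variance_explained = ve,
      cumulative = cumsum(ve)
    ),
    scores = scores
  ), class = "pca_summary")
}

#' @export
print.pca_summary <- function(x, ...) {
  cat("PCA of", nrow(x$scores), "samples;",
      sprintf("PC1 explains %.2f%% of variance\n",
              100 * x$variance$variance_explained[1]))
  invisible(x)
}
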