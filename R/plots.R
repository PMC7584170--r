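# ggplot2 displays for the main result types.

#' Genome-wide beta distribution by tissue
#'
#' Density of per-probe median methylation in each tissue; the polarisation of
#' the sperm methylome shows as heavier mass below 20% and above 80%.
#'
#' @param beta_blood,beta_sperm Probe x sample beta matrices.
#' @return A ggplot object.
#' @export
plot_beta_distribution <- function(beta_blood, beta_sperm) {
  df <- dplyr::bind_rows(
    tibble::tibble(tissue = "blood",
                   median_beta = matrixStats::rowMedians(beta_blood)),
    tibble::tibble(tissue = "sperm",
                   median_beta = matrixStats::rowMedians(beta_sperm))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$median_beta,
                                   colour = .data$tissue)) +
    ggplot2::geom_density() +
    ggplot2::labs(x = "median DNA methylation (beta)", y = "density") +
    ggplot2::theme_minimal()
}

#' Observed correlations against the permutation null
#'
#' Histogram of observed per-site cross-tissue correlations with the pooled
#' permutation-null density overlaid.
#'
#' @param object A `correlation_result` from [correlate_sites()].
#' @param null A `perm_null` from [permutation_null()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.correlation_result <- function(object, null = NULL, ...) {
  df <- tibble::tibble(r = object$r)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$r)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = 60, fill = "grey70") +
    ggplot2::labs(x = "cross-tissue Pearson r", y = "density") +
    ggplot2::theme_minimal()
  if (!is.null(null) && length(null$r)) {
    p <- p + ggplot2::geom_density(data = tibble::tibble(r = null$r),
                                   colour = "red")
  }
  p
}

#' Scatter of one probe's paired methylation across tissues
#'
#' @param beta_blood,beta_sperm Probe x sample beta matrices.
#' @param probe Probe ID.
#' @param clusters Optional integer cluster assignment (e.g. from
#'   [classify_modality_kmeans()]).
#' @return A ggplot object.
#' @export
plot_probe_scatter <- function(beta_blood, beta_sperm, probe, clusters = NULL) {
  df <- tibble::tibble(
    blood = beta_blood[probe, ],
    sperm = beta_sperm[probe, ],
    cluster = factor(clusters %||% rep(1L, ncol(beta_blood)))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$blood, y = .data$sperm,
                                   colour = .data$cluster)) +
    ggplot2::geom_point() +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(title = probe, x = "blood beta", y = "sperm beta") +
    ggplot2::theme_minimal()
}

#' Volcano-style display of an EWAS scan
#'
#' @param object An `ewas_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ewas_result <- function(object, ...) {
  df <- tibble::as_tibble(unclass_result(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$effect,
                                   y = -log10(.data$p.value),
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "effect (beta scale)", y = "-log10 p") +
    ggplot2::theme_minimal()
}

#' Variance-explained scree plot
#'
#' @param object A `pca_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.pca_summary <- function(object, ...) {
  ggplot2::ggplot(object$variance,
                  ggplot2::aes(x = .data$component,
                               y = .data$variance_explained)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "principal component", y = "variance explained") +
    ggplot2::theme_minimal()
}
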