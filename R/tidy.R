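# broom-style accessors for the package's result objects. The per-probe
# result classes are already tibbles; tidy() strips the class decoration and
# glance() reports the scan-level summary.

#' @exportS3Method generics::tidy
tidy.paired_test_result <- function(x, ...) tibble::as_tibble(unclass_result(x))

#' @exportS3Method generics::tidy
tidy.correlation_result <- function(x, ...) tibble::as_tibble(unclass_result(x))

#' @exportS3Method generics::tidy
tidy.ewas_result <- function(x, ...) tibble::as_tibble(unclass_result(x))

#' @exportS3Method generics::glance
glance.paired_test_result <- function(x, ...) {
  tibble::tibble(
    n_probes = nrow(x),
    n_tested = sum(!is.na(x$p.value)),
    n_significant = sum(x$significant, na.rm = TRUE),
    n_hyper_sperm = sum(x$significant & x$effect > 0, na.rm = TRUE),
    alpha = attr(x, "alpha")
  )
}

#' @exportS3Method generics::glance
glance.correlation_result <- function(x, ...) {
  tibble::tibble(
    n_probes = nrow(x),
    n_significant = sum(x$significant, na.rm = TRUE),
    n_negative = sum(x$significant & x$negative, na.rm = TRUE),
    median_r = median(x$r, na.rm = TRUE),
    alpha = attr(x, "alpha")
  )
}

#' @exportS3Method generics::glance
glance.ewas_result <- function(x, ...) {
  tibble::tibble(
    n_probes = nrow(x),
    n_tested = sum(!is.na(x$p.value)),
    n_significant = sum(x$significant, na.rm = TRUE),
    model = x$model[1],
    alpha = attr(x, "alpha")
  )
}

#' @exportS3Method generics::tidy
tidy.perm_null <- function(x, ...) {
  tibble::tibble(r = x$r)
}

#' @exportS3Method generics::glance
glance.perm_null <- function(x, ...) {
  tibble::tibble(
    n_perm = x$n_perm,
    n_pairs = x$n_pairs,
    n_probes = x$n_probes,
    n_pooled = length(x$r),
    sd_r = if (length(x$r)) sd(x$r) else NA_real_,
    sd_fisher_z = if (length(x$r)) sd(atanh(pmin(pmax(x$r, -1 + 1e-12), 1 - 1e-12))) else NA_real_
  )
}

#' @exportS3Method generics::tidy
tidy.pca_summary <- function(x, ...) x$variance

#' @exportS3Method generics::glance
glance.pca_summary <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$scores),
    n_components = nrow(x$variance),
    pc1_variance = x$variance$variance_explained[1]
  )
}

unclass_result <- function(x) {
  cls <- class(x)
  class(x) <- cls[!cls %in% c("paired_test_result", "correlation_result",
                              "ewas_result")]
  x
}
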