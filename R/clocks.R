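#' Define an epigenetic clock
#'
#' An epigenetic clock is a sparse linear predictor over CpG beta values plus
#' an output transform. The `"log-linear-age"` transform is the piecewise
#' transform used by multi-tissue age estimators: for a linear score s,
#' predicted age is `(1 + adult_age) * exp(s) - 1` when `s < 0` and
#' `(1 + adult_age) * s + adult_age` otherwise; it is continuous and strictly
#' increasing with value `adult_age` at `s = 0`.
#'
#' @param name Clock name.
#' @param intercept Intercept of the linear predictor.
#' @param coefficients Named numeric vector: probe ID -> weight (non-empty).
#' @param transform `"identity"` or `"log-linear-age"`.
#' @param adult_age Breakpoint in years for the log-linear transform
#'   (default 20).
#' @return Object of class `clock_definition`.
#' @export
clock_definition <- function(name, intercept, coefficients,
                             transform = c("identity", "log-linear-age"),
                             adult_age = 20) {
  transform <- match.arg(transform)
  if (length(coefficients) == 0 || is.null(names(coefficients))) {
    stop("`coefficients` must be a non-empty named vector", call. = FALSE)
  }
  structure(list(name = name, intercept = intercept,
                 coefficients = coefficients, transform = transform,
                 adult_age = adult_age),
            class = "clock_definition")
}

#' @export
print.clock_definition <- function(x, ...) {
  cat("Epigenetic clock `", x$name, "`: ", length(x$coefficients),
      " CpGs, transform = ", x$transform, "\n", sep = "")
  invisible(x)
}

clock_transform <- function(s, transform, adult_age) {
  if (transform == "identity") return(s)
  ifelse(s < 0, (1 + adult_age) * exp(s) - 1, (1 + adult_age) * s + adult_age)
}

#' Apply an epigenetic clock to a beta matrix
#'
#' Computes the linear predictor `intercept + sum(coef * beta)` per sample and
#' applies the clock's output transform. A clock probe absent from the matrix
#' is imputed at the cohort mean beta of the available clock probes (the
#' usual cohort-mean imputation convention, logged via `n_missing_probes`);
#' at least 80% of clock probes must be present, otherwise an error lists the
#' missing probes.
#'
#' @param beta Probe x sample beta matrix.
#' @param clock A [clock_definition()].
#' @return Tibble: `sample`, `dnam_age` (years), `n_missing_probes`.
#' @export
apply_clock <- function(beta, clock) {
  assert_beta_matrix(beta)
  probes <- names(clock$coefficients)
  present <- probes %in% rownames(beta)
  if (mean(present) < 0.8) {
    stop("fewer than 80% of clock probes present; missing: ",
         paste(head(probes[!present], 10), collapse = ", "),
         if (sum(!present) > 10) ", ..." else "", call. = FALSE)
  }
  B <- beta[probes[present], , drop = FALSE]
  s <- clock$intercept + drop(crossprod(B, clock$coefficients[present]))
  if (any(!present)) {
    # impute each absent probe at the cohort mean beta of the probes we have
    imput <- mean(B)
    s <- s + sum(clock$coefficients[!present]) * imput
  }
  tibble::tibble(
    sample = colnames(beta),
    dnam_age = unname(clock_transform(s, clock$transform, clock$adult_age)),
    n_missing_probes = sum(!present)
  )
}

#' Age acceleration as residual DNAm age
#'
#' Residuals of the ordinary regression of DNAm age on chronological age
#' (plus optional covariates such as estimated cell fractions): positive
#' values mean epigenetically older than expected. Residuals are orthogonal
#' to the regressors and sum to zero.
#'
#' @param dnam_age Numeric vector of DNAm ages (years), or the tibble from
#'   [apply_clock()].
#' @param chron_age Numeric vector of chronological ages (same order).
#' @param covariates Optional data frame of additional regressors (e.g. cell
#'   fractions for blood).
#' @return Tibble: `sample` (if available), `dnam_age`, `chron_age`,
#'   `acceleration` (years).
#' @export
age_acceleration <- function(dnam_age, chron_age, covariates = NULL) {
  samples <- NULL
  if (is.data.frame(dnam_age)) {
    samples <- dnam_age$sample
    dnam_age <- dnam_age$dnam_age
  }
  if (length(dnam_age) != length(chron_age)) {
    stop("`dnam_age` and `chron_age` lengths differ", call. = FALSE)
  }
  if (length(dnam_age) < 4) stop("need at least 4 samples", call. = FALSE)
  if (sd(chron_age) == 0) stop("constant chronological age: residuals undefined", call. = FALSE)
  dat <- data.frame(dnam_age = dnam_age, chron_age = chron_age)
  if (!is.null(covariates)) dat <- cbind(dat, as.data.frame(covariates))
  fit <- stats::lm(dnam_age ~ ., data = dat)
  tibble::tibble(
    sample = samples %||% as.character(seq_along(dnam_age)),
    dnam_age = dnam_age,
    chron_age = chron_age,
    acceleration = unname(resid(fit))
  )
}

#' Associations between age acceleration and metabolic traits
#'
#' One simple ordinary regression of acceleration on each trait (e.g. BMI,
#' obesity indicator, waist circumference, HOMA-IR, fasting insulin),
#' reporting slope and two-sided p per trait. A constant trait, or a
#' degenerate all-zero acceleration vector, yields the `slope = 0, p = 1`
#' convention (`NA` slope for the constant trait).
#'
#' @param acceleration Numeric vector or the tibble from [age_acceleration()].
#' @param traits Data frame of numeric traits, one row per sample.
#' @return Tibble: `trait`, `slope`, `se`, `statistic`, `p.value`, `n`.
#' @export
acceleration_associations <- function(acceleration, traits) {
  if (is.data.frame(acceleration)) acceleration <- acceleration$acceleration
  if (nrow(traits) != length(acceleration)) {
    stop("`traits` must have one row per sample", call. = FALSE)
  }
  purrr::imap(as.list(traits), function(x, nm) {
    ok <- stats::complete.cases(x, acceleration)
    x <- as.numeric(x[ok]); y <- acceleration[ok]
    if (sd(x) == 0) {
      return(tibble::tibble(trait = nm, slope = NA_real_, se = NA_real_,
                            statistic = NA_real_, p.value = NA_real_,
                            n = length(x)))
    }
    if (sd(y) == 0) {
      return(tibble::tibble(trait = nm, slope = 0, se = NA_real_,
                            statistic = NA_real_, p.value = 1, n = length(x)))
    }
    fit <- summary(stats::lm(y ~ x))
    cf <- fit$coefficients
    tibble::tibble(trait = nm, slope = cf[2, 1], se = cf[2, 2],
                   statistic = cf[2, 3], p.value = cf[2, 4], n = length(x))
  }) |> dplyr::bind_rows()
}
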