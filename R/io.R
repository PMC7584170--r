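#' Read and write probe-by-sample matrices
#'
#' Matrices travel as (optionally gzip-compressed) TSV with a header row of
#' sample IDs and the probe ID in the first column.
#'
#' @param beta Probe x sample numeric matrix.
#' @param path Output path; a `.gz` suffix compresses.
#' @return `write_beta_matrix` returns `path` invisibly; `read_beta_matrix`
#'   returns a numeric matrix with probe rownames.
#' @export
write_beta_matrix <- function(beta, path) {
  df <- tibble::as_tibble(beta, rownames = "probe_id")
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_beta_matrix
#' @export
read_beta_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Read a plain-text probe list (one probe ID per line)
#'
#' @param path Path to the list file.
#' @return Character vector of probe IDs.
#' @export
read_probe_list <- function(path) {
  x <- readr::read_lines(path, progress = FALSE)
  x[nzchar(trimws(x))]
}

#' Read a BED3+ interval file
#'
#' Intervals are 0-based half-open per the BED convention and are returned
#' that way (conversion to 1-based coordinates happens inside
#' [interval_overlap()]).
#'
#' @param path Path to a BED file.
#' @return Tibble: `chr`, `start`, `end` (plus `name` when present).
#' @export
read_bed <- function(path) {
  df <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                        show_col_types = FALSE, progress = FALSE)
  if (ncol(df) < 3) stop("BED file needs at least 3 columns", call. = FALSE)
  out <- tibble::tibble(chr = as.character(df[[1]]),
                        start = as.integer(df[[2]]),
                        end = as.integer(df[[3]]))
  if (ncol(df) >= 4) out$name <- as.character(df[[4]])
  out
}

#' Write a QC report as JSON
#'
#' @param report A `qc_report` from [filter_probes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  jsonlite::write_json(
    list(
      n_input = report$n_input,
      n_retained = report$n_retained,
      removed = report$removed,
      filter_order = report$filter_order,
      thresholds = report$thresholds
    ),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' Read and write clock coefficient tables
#'
#' The CSV format carries a header block of `#`-prefixed key-value lines
#' (`name`, `intercept`, `transform`, `adult_age`) followed by
#' `probe_id,coefficient` rows.
#'
#' @param clock A [clock_definition()].
#' @param path File path.
#' @return `write_clock` returns `path` invisibly; `read_clock` returns a
#'   [clock_definition()].
#' @export
write_clock <- function(clock, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# name=", clock$name),
    paste0("# intercept=", format(clock$intercept, digits = 17)),
    paste0("# transform=", clock$transform),
    paste0("# adult_age=", format(clock$adult_age, digits = 17)),
    "probe_id,coefficient"
  ), con)
  writeLines(paste(names(clock$coefficients),
                   format(clock$coefficients, digits = 17, trim = TRUE),
                   sep = ","), con)
  invisible(path)
}

#' @rdname write_clock
#' @export
read_clock <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  kv <- strsplit(sub("^#\\s*", "", hdr), "=", fixed = TRUE)
  meta <- setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  body <- lines[!startsWith(lines, "#")]
  df <- readr::read_csv(I(paste(body, collapse = "\n")),
                        show_col_types = FALSE, progress = FALSE)
  clock_definition(
    name = meta[["name"]],
    intercept = as.numeric(meta[["intercept"]]),
    coefficients = setNames(df$coefficient, df$probe_id),
    transform = meta[["transform"]],
    adult_age = as.numeric(meta[["adult_age"]])
  )
}

#' Write a generated cohort to disk
#'
#' Beta, detection-p and bead-count matrices go to gzip TSV; the sample
#' sheet, truth table and annotation to CSV (SNP offsets in long form); and
#' the probe coordinates to a companion BED (0-based half-open) per interval
#' class.
#'
#' @param cohort A `cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(dir, ...)
  write_beta_matrix(cohort$blood, fp("beta_blood.tsv.gz"))
  write_beta_matrix(cohort$sperm, fp("beta_sperm.tsv.gz"))
  for (tis in c("blood", "sperm")) {
    write_beta_matrix(cohort$detp[[tis]], fp(paste0("detp_", tis, ".tsv.gz")))
    write_beta_matrix(cohort$beads[[tis]], fp(paste0("beads_", tis, ".tsv.gz")))
  }
  readr::write_csv(cohort$sample_sheet, fp("sample_sheet.csv"))
  ann <- cohort$annotation
  readr::write_csv(ann[setdiff(names(ann), "snp_offsets")], fp("annotation.csv"))
  snp_long <- tidyr::unnest(
    ann[c("probe_id", "snp_offsets")],
    "snp_offsets"
  )
  readr::write_csv(snp_long, fp("snp_offsets.csv"))
  truth <- cohort$truth
  geno <- vapply(truth$genotype, function(g) {
    if (is.null(g)) NA_character_ else paste(g, collapse = ";")
  }, character(1))
  out_truth <- truth[setdiff(names(truth), "genotype")]
  out_truth$genotype <- geno
  readr::write_csv(out_truth, fp("truth.csv"))
  # BED of imprinted-probe positions (1-based position -> 0-based half-open)
  imp <- ann[ann$imprint_class != "none", ]
  if (nrow(imp)) {
    readr::write_tsv(
      tibble::tibble(chr = imp$chr, start = imp$position - 1L,
                     end = imp$position, name = imp$probe_id),
      fp("imprinted.bed"), col_names = FALSE)
  }
  invisible(dir)
}
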