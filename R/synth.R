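#' Simulation configuration for a matched two-tissue methylation cohort
#'
#' Defines the study conditions for the bundled cohort generator: a discovery-
#' plus-replication-sized cohort of matched blood and sperm methylomes with
#' planted signal classes and full ground truth. Defaults mirror the combined
#' cohort the package's analyses are designed around (68 lean + 22 obese men,
#' a planted cross-tissue obesity shift of 2% DNA methylation, common
#' gap-signal variants at minor allele frequency 0.4).
#'
#' Signal classes planted among probes (remainder are null):
#' \describe{
#'   \item{snp_bimodal}{two methylation levels tracking carrier status of a
#'     variant shared across tissues (Hardy-Weinberg genotypes at `maf`).}
#'   \item{snp_trimodal}{three levels tracking allele dosage 0/1/2, identical
#'     genotype in both tissues (strong positive cross-tissue correlation).}
#'   \item{negative_correlated}{dosage effect applied with opposite sign in
#'     the two tissues, yielding negatively correlated sites.}
#'   \item{outlier_driven}{one randomly chosen individual displaced by
#'     `outlier_shift` in both tissues; all other individuals are null.}
#'   \item{imprinted}{parent-of-origin pattern: centred at 50% methylation in
#'     blood, essentially unmethylated in sperm.}
#'   \item{obesity_associated}{methylation raised by `obesity_effect` in obese
#'     individuals, in both tissues.}
#' }
#'
#' @param n_individuals Number of individuals (matched pairs). Must be >= 4.
#' @param n_probes Number of probes.
#' @param class_fractions Named numeric vector of planted-class fractions over
#'   probes; names from the classes above. Must sum to <= 1; the remainder is
#'   null.
#' @param maf Minor allele frequency for SNP-driven classes, in `[0, 1]`.
#' @param obesity_effect Beta-scale shift planted at obesity-associated sites
#'   (default 0.02, i.e. 2% DNA methylation).
#' @param noise_sd Beta-scale standard deviation of the truncated-normal
#'   measurement noise.
#' @param individual_sd Beta-scale standard deviation of the per-individual
#'   random intercept shared across tissues (inter-individual variation the
#'   cross-tissue mixed model absorbs; also shifts the observed null
#'   correlation distribution slightly right of the permutation null, as seen
#'   in real cohorts). Set to 0 for fully independent tissues.
#' @param n_obese Number of obese individuals (BMI > 26); the rest are lean.
#' @param batch_assignment Optional integer/character vector of length
#'   `n_individuals` mapping individual to processing batch; default splits
#'   the cohort into two batches.
#' @param cell_fractions_alpha Dirichlet concentration parameters for blood
#'   cell mixing (used by [generate_reference_profiles()]); default is a
#'   granulocyte-dominated six-type blood profile.
#' @param polarise Logical; if `TRUE` (default) sperm baselines are drawn from
#'   a more polarised genome-wide distribution than blood (more mass below 20%
#'   and above 80% methylation) and the two tissues' baselines are drawn
#'   independently. If `FALSE` the tissues share identical baselines (a null
#'   configuration for paired-test calibration).
#' @param batch_effect_sd Standard deviation of the per-probe shift applied to
#'   second-batch samples at `batch_effect_fraction` of probes (both tissues).
#' @param batch_effect_fraction Fraction of probes carrying a batch effect.
#' @param failure_rate Fraction of probe-sample cells given a failed detection
#'   p-value / low bead count, so QC filters have work to do.
#' @param outlier_shift Displacement applied to the single outlying individual
#'   at outlier-driven sites.
#' @param seed Integer seed; identical configurations generate identical
#'   cohorts.
#'
#' @return An object of class `sim_config` (a named list).
#' @seealso [generate_cohort()]
#' @export
sim_config <- function(n_individuals = 90,
                       n_probes = 2000,
                       class_fractions = c(
                         snp_bimodal = 0.02,
                         snp_trimodal = 0.02,
                         negative_correlated = 0.005,
                         outlier_driven = 0.005,
                         imprinted = 0.01,
                         obesity_associated = 0.005
                       ),
                       maf = 0.4,
                       obesity_effect = 0.02,
                       noise_sd = 0.02,
                       individual_sd = 0.01,
                       n_obese = 22,
                       batch_assignment = NULL,
                       cell_fractions_alpha = c(
                         mono = 0.8, gran = 5.5, nk = 0.4,
                         bcell = 0.6, cd8t = 1.0, cd4t = 1.7
                       ),
                       polarise = TRUE,
                       batch_effect_sd = 0.005,
                       batch_effect_fraction = 0.2,
                       failure_rate = 0.005,
                       outlier_shift = 0.5,
                       seed = 1L) {
  known <- c("snp_bimodal", "snp_trimodal", "negative_correlated",
             "outlier_driven", "imprinted", "obesity_associated")
  cf <- setNames(rep(0, length(known)), known)
  if (length(class_fractions)) {
    bad <- setdiff(names(class_fractions), known)
    if (length(bad)) stop("unknown signal class(es): ", paste(bad, collapse = ", "), call. = FALSE)
    cf[names(class_fractions)] <- class_fractions
  }
  if (any(cf < 0 | cf > 1)) stop("class fractions must lie in [0, 1]", call. = FALSE)
  if (sum(cf) > 1) stop("class fractions sum to more than 1", call. = FALSE)
  if (maf < 0 || maf > 1) stop("`maf` must lie in [0, 1]", call. = FALSE)
  if (n_obese > n_individuals) stop("`n_obese` cannot exceed `n_individuals`", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)
  if (individual_sd < 0) stop("`individual_sd` must be non-negative", call. = FALSE)
  if (failure_rate < 0 || failure_rate > 1) stop("`failure_rate` must lie in [0, 1]", call. = FALSE)
  if (!is.null(batch_assignment) && length(batch_assignment) != n_individuals) {
    stop("`batch_assignment` must have one entry per individual", call. = FALSE)
  }
  structure(list(
    n_individuals = as.integer(n_individuals),
    n_probes = as.integer(n_probes),
    class_fractions = cf,
    maf = maf,
    obesity_effect = obesity_effect,
    noise_sd = noise_sd,
    individual_sd = individual_sd,
    n_obese = as.integer(n_obese),
    batch_assignment = batch_assignment,
    cell_fractions_alpha = cell_fractions_alpha,
    polarise = isTRUE(polarise),
    batch_effect_sd = batch_effect_sd,
    batch_effect_fraction = batch_effect_fraction,
    failure_rate = failure_rate,
    outlier_shift = outlier_shift,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Per-tissue, per-CpG-region probabilities of a probe's baseline falling in the
# low (< 20%), intermediate or high (> 80%) methylation category. Chosen so the
# genome-wide mixture reproduces the polarisation seen on arrays: sperm has
# more mass at both extremes than blood, and CpG islands are hypomethylated.
.baseline_weights <- list(
  blood = list(island   = c(0.60, 0.30, 0.10),
               shore    = c(0.45, 0.35, 0.20),
               shelf    = c(0.15, 0.35, 0.50),
               open_sea = c(0.10, 0.30, 0.60)),
  sperm = list(island   = c(0.75, 0.15, 0.10),
               shore    = c(0.55, 0.20, 0.25),
               shelf    = c(0.10, 0.15, 0.75),
               open_sea = c(0.08, 0.12, 0.80))
)

.draw_baseline <- function(region, tissue) {
  w <- .baseline_weights[[tissue]]
  n <- length(region)
  cat3 <- vapply(region, function(rg) {
    sample.int(3L, 1L, prob = w[[rg]])
  }, integer(1))
  lo <- runif(n, 0.02, 0.15)
  mid <- runif(n, 0.25, 0.75)
  hi <- runif(n, 0.85, 0.98)
  ifelse(cat3 == 1L, lo, ifelse(cat3 == 2L, mid, hi))
}

#' Generate a matched blood-sperm cohort with planted ground truth
#'
#' Draws a full synthetic cohort under the study conditions of a
#' [sim_config()]: probe-by-individual beta matrices for blood and sperm,
#' matching detection-p and bead-count matrices, a per-individual sample sheet,
#' a probe annotation table, and the planted truth mapping every probe to its
#' generative class.
#'
#' Measurement noise is truncated-normal on the proportion scale (clipped to
#' `[0, 1]`), so planted effects read directly as "% DNA methylation". SNP-class
#' sites share a single Hardy-Weinberg genotype per individual across both
#' tissues; imprinted sites are centred at 0.5 in blood and below 0.05 in
#' sperm; obesity-class sites are shifted by `obesity_effect` in obese
#' individuals in both tissues.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `cohort` with elements `blood`, `sperm` (beta
#'   matrices, probes x individuals), `detp`, `beads` (lists with `blood` and
#'   `sperm` matrices of the same shape), `sample_sheet` (tibble, one row per
#'   individual), `annotation` (tibble, one row per probe), and `truth`
#'   (tibble, one row per probe; `genotype` is a list-column of per-individual
#'   allele dosages at SNP-driven sites).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_individuals < 4L) {
    stop("need at least 4 individuals (paired tests undefined below that)", call. = FALSE)
  }
  set.seed(config$seed)
  n <- config$n_individuals
  m <- config$n_probes
  individuals <- sprintf("ind%03d", seq_len(n))
  probes <- sprintf("cg%07d", seq_len(m))

  ## sample sheet ------------------------------------------------------------
  obese_idx <- if (config$n_obese > 0) sample.int(n, config$n_obese) else integer(0)
  obesity <- as.integer(seq_len(n) %in% obese_idx)
  batch <- config$batch_assignment
  if (is.null(batch)) batch <- rep_len(c(1L, 2L), n)
  age <- round(runif(n, 25, 45), 1)
  bmi <- ifelse(obesity == 1,
                round(pmax(rnorm(n, 29, 2), 26.1), 1),
                round(pmin(pmax(rnorm(n, 22.5, 1.5), 19), 25), 1))
  waist <- round(bmi * 2.6 + rnorm(n, 0, 4), 1)
  homa_ir <- round(exp(rnorm(n, log(1.1) + 0.06 * (bmi - 23), 0.35)), 2)
  fasting_insulin <- round(homa_ir * 22.5 / 5 + rnorm(n, 0, 0.8), 2)
  sample_sheet <- tibble::tibble(
    individual = individuals,
    group = ifelse(obesity == 1, "obese", "lean"),
    obesity = obesity,
    age = age,
    bmi = bmi,
    batch = factor(batch),
    waist_circumference = waist,
    homa_ir = homa_ir,
    fasting_insulin = fasting_insulin
  )

  ## probe classes -----------------------------------------------------------
  cf <- config$class_fractions
  counts <- floor(cf * m)
  classes <- rep("null", m)
  pos <- 1L
  for (cl in names(counts)) {
    k <- counts[[cl]]
    if (k > 0) {
      classes[pos:(pos + k - 1L)] <- cl
      pos <- pos + k
    }
  }
  classes <- classes[sample.int(m)]

  ## annotation --------------------------------------------------------------
  cpg_region <- sample(c("island", "shore", "shelf", "open_sea"), m,
                       replace = TRUE, prob = c(0.20, 0.20, 0.10, 0.50))
  genomic_region <- sample(
    c("tss200", "tss1500", "utr5", "first_exon", "body", "utr3", "intergenic"),
    m, replace = TRUE, prob = c(0.06, 0.08, 0.06, 0.04, 0.36, 0.04, 0.36))
  chr <- sample(paste0("chr", 1:22), m, replace = TRUE)
  position <- sample.int(1e8L, m, replace = TRUE)
  probe_type <- sample(c("I", "II"), m, replace = TRUE, prob = c(0.16, 0.84))
  on_450k <- runif(m) < 0.5
  snp_class <- classes %in% c("snp_bimodal", "snp_trimodal", "negative_correlated")
  # SNP-driven sites carry a variant at the CpG site itself; a sprinkling of
  # null probes gets probe-body SNPs so distance annotation has work to do.
  snp_offsets <- vector("list", m)
  snp_offsets[snp_class] <- list(0L)
  body_snp <- which(!snp_class & runif(m) < 0.02)
  snp_offsets[body_snp] <- lapply(body_snp, function(i) sample(2:45, sample(1:2, 1)))
  imprint_class <- rep("none", m)
  imprint_class[classes == "imprinted"] <-
    sample(c("known_paternal", "known_maternal"), sum(classes == "imprinted"),
           replace = TRUE, prob = c(0.6, 0.4))
  annotation <- tibble::tibble(
    probe_id = probes,
    chr = chr,
    position = position,
    cpg_region = cpg_region,
    genomic_region = genomic_region,
    probe_type = probe_type,
    on_450k = on_450k,
    imprint_class = imprint_class,
    snp_offsets = snp_offsets
  )

  ## baseline means ----------------------------------------------------------
  base_blood <- .draw_baseline(cpg_region, "blood")
  base_sperm <- if (config$polarise) .draw_baseline(cpg_region, "sperm") else base_blood

  mean_blood <- matrix(base_blood, m, n)
  mean_sperm <- matrix(base_sperm, m, n)

  genotype <- vector("list", m)
  true_effect <- numeric(m)
  outlier_individual <- rep(NA_character_, m)

  for (i in which(snp_class)) {
    g <- rbinom(n, 2L, config$maf)
    genotype[[i]] <- g
    cl <- classes[i]
    if (cl == "snp_bimodal") {
      lv <- 0.10 + 0.80 * (g >= 1L)
      mean_blood[i, ] <- lv
      mean_sperm[i, ] <- lv
      true_effect[i] <- 0.80
    } else if (cl == "snp_trimodal") {
      lv <- 0.05 + 0.45 * g
      mean_blood[i, ] <- lv
      mean_sperm[i, ] <- lv
      true_effect[i] <- 0.45
    } else { # negative_correlated: dosage effect with opposite sign per tissue
      mean_blood[i, ] <- 0.05 + 0.45 * g
      mean_sperm[i, ] <- 0.95 - 0.45 * g
      true_effect[i] <- 0.45
    }
  }
  for (i in which(classes == "outlier_driven")) {
    base <- runif(1, 0.05, 0.25)
    mean_blood[i, ] <- base
    mean_sperm[i, ] <- base
    who <- sample.int(n, 1L)
    mean_blood[i, who] <- clip01(base + config$outlier_shift)
    mean_sperm[i, who] <- clip01(base + config$outlier_shift)
    outlier_individual[i] <- individuals[who]
    true_effect[i] <- config$outlier_shift
  }
  imp <- classes == "imprinted"
  if (any(imp)) {
    mean_blood[imp, ] <- 0.5
    mean_sperm[imp, ] <- 0.02
    true_effect[imp] <- 0.48
  }
  ob <- classes == "obesity_associated"
  if (any(ob)) {
    base <- runif(sum(ob), 0.3, 0.7)
    mean_blood[ob, ] <- base
    mean_sperm[ob, ] <- base
    if (length(obese_idx)) {
      mean_blood[ob, obese_idx] <- mean_blood[ob, obese_idx] + config$obesity_effect
      mean_sperm[ob, obese_idx] <- mean_sperm[ob, obese_idx] + config$obesity_effect
    }
    true_effect[ob] <- config$obesity_effect
  }

  ## batch effect ------------------------------------------------------------
  if (config$batch_effect_sd > 0 && config$batch_effect_fraction > 0) {
    batched <- which(runif(m) < config$batch_effect_fraction)
    b2 <- which(batch == sort(unique(batch))[min(2, length(unique(batch)))])
    if (length(batched) && length(b2) && length(unique(batch)) > 1) {
      shift <- rnorm(length(batched), 0, config$batch_effect_sd)
      mean_blood[batched, b2] <- mean_blood[batched, b2] + shift
      mean_sperm[batched, b2] <- mean_sperm[batched, b2] + shift
    }
  }

  ## per-individual random intercept (shared across tissues) ------------------
  if (config$individual_sd > 0) {
    ind_fx <- matrix(rnorm(m * n, 0, config$individual_sd), m, n)
    mean_blood <- mean_blood + ind_fx
    mean_sperm <- mean_sperm + ind_fx
  }

  ## noise + clipping --------------------------------------------------------
  noisy <- function(mu) {
    x <- mu
    if (config$noise_sd > 0) x <- x + rnorm(length(mu), 0, config$noise_sd)
    clip01(matrix(x, m, n, dimnames = list(probes, individuals)))
  }
  blood <- noisy(mean_blood)
  sperm <- noisy(mean_sperm)

  ## detection p / bead counts ----------------------------------------------
  gen_detp <- function() {
    d <- matrix(runif(m * n, 0, 1e-3), m, n, dimnames = list(probes, individuals))
    fail <- which(runif(m * n) < config$failure_rate)
    d[fail] <- runif(length(fail), 0.05 + 1e-9, 1)
    d
  }
  gen_beads <- function() {
    b <- matrix(sample(5:25, m * n, replace = TRUE), m, n,
                dimnames = list(probes, individuals))
    fail <- which(runif(m * n) < config$failure_rate)
    b[fail] <- sample(1:2, length(fail), replace = TRUE)
    b
  }

  truth <- tibble::tibble(
    probe_id = probes,
    signal_class = classes,
    true_effect = true_effect,
    outlier_individual = outlier_individual,
    genotype = genotype
  )

  structure(list(
    blood = blood,
    sperm = sperm,
    detp = list(blood = gen_detp(), sperm = gen_detp()),
    beads = list(blood = gen_beads(), sperm = gen_beads()),
    sample_sheet = sample_sheet,
    annotation = annotation,
    truth = truth,
    config = config
  ), class = "cohort")
}

#' Generate cell-type reference profiles and mixed blood samples
#'
#' Builds distinguishable methylation reference profiles for `n_celltypes`
#' blood cell types (each type has a block of marker probes where it is highly
#' methylated and the others are not), draws per-individual mixing fractions
#' from a Dirichlet distribution with the configuration's concentration
#' parameters, and emits marker-probe blood betas as convex combinations of
#' the profiles plus truncated-normal noise.
#'
#' @param config A [sim_config()] object (supplies `n_individuals`,
#'   `cell_fractions_alpha`, `noise_sd` and `seed`).
#' @param n_celltypes Number of cell types (>= 1).
#' @param n_markers_per_type Marker probes per cell type.
#' @param fractions Optional matrix (individuals x cell types) of mixing
#'   fractions to use instead of Dirichlet draws; rows must sum to 1.
#' @return List with `reference` (marker probes x cell types), `fractions`
#'   (individuals x cell types, rows summing to 1), and `beta` (marker probes
#'   x individuals).
#' @export
generate_reference_profiles <- function(config, n_celltypes = 6,
                                        n_markers_per_type = 20,
                                        fractions = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (n_celltypes < 1) stop("`n_celltypes` must be at least 1", call. = FALSE)
  if (n_markers_per_type < 1) {
    stop("`n_celltypes` exceeds the distinguishable-marker capacity: ",
         "need at least one marker probe per cell type", call. = FALSE)
  }
  set.seed(config$seed + 1L)
  n <- config$n_individuals
  k <- n_celltypes
  types <- if (k == 6 && length(config$cell_fractions_alpha) == 6) {
    names(config$cell_fractions_alpha)
  } else {
    paste0("celltype", seq_len(k))
  }
  mp <- n_markers_per_type
  probes <- sprintf("cellmk%04d", seq_len(k * mp))
  reference <- matrix(runif(k * mp * k, 0.02, 0.10), k * mp, k,
                      dimnames = list(probes, types))
  for (j in seq_len(k)) {
    rows <- ((j - 1L) * mp + 1L):(j * mp)
    reference[rows, j] <- runif(mp, 0.85, 0.98)
  }
  if (is.null(fractions)) {
    alpha <- rep_len(config$cell_fractions_alpha, k)
    g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), n, k)
    fractions <- g / rowSums(g)
  } else {
    fractions <- as.matrix(fractions)
    if (ncol(fractions) != k || nrow(fractions) != n) {
      stop("`fractions` must be n_individuals x n_celltypes", call. = FALSE)
    }
    if (any(abs(rowSums(fractions) - 1) > 1e-8)) {
      stop("rows of `fractions` must sum to 1", call. = FALSE)
    }
  }
  dimnames(fractions) <- list(sprintf("ind%03d", seq_len(n)), types)
  beta <- reference %*% t(fractions)
  if (config$noise_sd > 0) {
    beta <- beta + rnorm(length(beta), 0, config$noise_sd)
  }
  beta <- clip01(beta)
  dimnames(beta) <- list(probes, rownames(fractions))
  list(reference = reference, fractions = fractions, beta = beta)
}

#' Generate a synthetic epigenetic clock consistent with generated betas
#'
#' Constructs clock probes whose methylation is linear in (transformed)
#' chronological age, plus a coefficient table that inverts the construction:
#' applying the emitted clock to the emitted beta block recovers chronological
#' age up to the configured noise (exactly, when `noise_sd = 0`).
#'
#' @param config A [sim_config()] object (supplies `noise_sd` and `seed`).
#' @param ages Numeric vector of chronological ages in years, one per sample;
#'   names (if present) become sample identifiers.
#' @param n_clock_probes Number of clock CpGs.
#' @param transform `"identity"` or `"log-linear-age"` (the piecewise
#'   log-linear age transform used by multi-tissue clocks, with its breakpoint
#'   at `adult_age`).
#' @param adult_age Breakpoint (years) of the log-linear transform.
#' @return List with `clock` (a [clock_definition()]) and `beta` (clock probes
#'   x samples).
#' @export
generate_clock <- function(config, ages, n_clock_probes = 30,
                           transform = c("identity", "log-linear-age"),
                           adult_age = 20) {
  stopifnot(inherits(config, "sim_config"))
  transform <- match.arg(transform)
  if (length(ages) == 0) stop("`ages` must be non-empty", call. = FALSE)
  set.seed(config$seed + 2L)
  n <- length(ages)
  samples <- if (!is.null(names(ages))) names(ages) else sprintf("sample%03d", seq_len(n))
  target <- if (transform == "identity") {
    ages
  } else {
    ifelse(ages < adult_age,
           log(ages + 1) - log(adult_age + 1),
           (ages - adult_age) / (adult_age + 1))
  }
  m <- n_clock_probes
  probes <- sprintf("clk%04d", seq_len(m))
  if (transform == "identity") {
    slope <- runif(m, 0.004, 0.010)
    a0 <- runif(m, 0.05, 0.30)
  } else {
    slope <- runif(m, 0.08, 0.14)
    a0 <- runif(m, 0.35, 0.50)
  }
  beta <- outer(slope, target) + a0
  if (config$noise_sd > 0) beta <- beta + rnorm(length(beta), 0, config$noise_sd)
  beta <- clip01(matrix(beta, m, n, dimnames = list(probes, samples)))
  w <- 1 / (m * slope)
  clock <- clock_definition(
    name = "synthetic",
    intercept = -sum(w * a0),
    coefficients = setNames(w, probes),
    transform = transform,
    adult_age = adult_age
  )
  list(clock = clock, beta = beta)
}
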