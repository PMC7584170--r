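# Shared fixtures, built in code at test time.

# A small default cohort reused across module tests (47 matched pairs, all
# planted classes present in useful numbers).
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(
        n_individuals = 47, n_probes = 1500, n_obese = 0,
        class_fractions = c(snp_bimodal = 0.03, snp_trimodal = 0.03,
                            negative_correlated = 0.01, outlier_driven = 0.01,
                            imprinted = 0.02),
        seed = 101
      )
      cache <<- generate_cohort(cfg)
    }
    cache
  }
})

# Null configuration: identical tissue baselines, independent noise only.
null_config <- function(n_individuals = 20, n_probes = 200, seed = 1,
                        noise_sd = 0.02, individual_sd = 0, n_obese = 5) {
  sim_config(n_individuals = n_individuals, n_probes = n_probes,
             n_obese = n_obese, class_fractions = c(), polarise = FALSE,
             batch_effect_sd = 0, noise_sd = noise_sd,
             individual_sd = individual_sd, seed = seed)
}

# Tiny deterministic beta matrix with probe/sample names.
toy_beta <- function(values, n_probes, n_samples, prefix = "cg") {
  matrix(values, n_probes, n_samples,
         dimnames = list(sprintf("%s%03d", prefix, seq_len(n_probes)),
                         sprintf("s%02d", seq_len(n_samples))))
}

probes_of_class <- function(cohort, class) {
  cohort$truth$probe_id[cohort$truth$signal_class == class]
}
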