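# shared fixtures and configuration shortcuts, all built in code

no_flags <- function() {
  setNames(rep(0, 6),
           c("consent_withdrawn", "sex_mismatch", "related", "non_british",
             "icd10_mental_neuro", "neuroticism_missing"))
}

# a clean analysis cohort: no exclusions, everyone employed, continuous outcome
clean_config <- function(n_samples, seed, ...) {
  sim_config(n_samples = n_samples, seed = seed, outcome_scale = "latent",
             flag_rates = no_flags(), employment_rate = 1, ...)
}

analysis_covariates <- c("age", "sex", "centre", "tdi")

trait_z_cols <- c(neuroticism = "z_neuroticism", education = "z_education",
                  physical_activity = "z_met")

add_grs <- function(cohort, sim, traits = names(trait_z_cols)) {
  for (t in traits) {
    cohort[[paste0("grs_", t)]] <-
      unname(compute_unweighted_grs(sim$genotypes, sim$instruments, t)$score)
  }
  cohort
}

# small hand-built genotype matrix for unit tests
toy_genotypes <- function(dosages = rbind(c(0, 1), c(1, 2), c(2, 0)),
                          traits = c("neuroticism", "neuroticism")) {
  m <- ncol(dosages)
  eaf <- colMeans(dosages, na.rm = TRUE) / 2
  eaf[!is.finite(eaf)] <- 0.5
  genotype_matrix(dosages,
                  data.frame(variant_id = paste0("v", seq_len(m)),
                             effect_allele = rep("A", m),
                             other_allele = rep("G", m),
                             eaf = eaf,
                             trait = traits,
                             stringsAsFactors = FALSE),
                  sample_ids = paste0("S", seq_len(nrow(dosages))))
}

# deterministic outlier-free standard sample: truncated normal quantiles,
# rescaled to exact mean 0 / sd 1 (max |z| ~ 2.6, well inside 3.29)
trimmed_base <- function(n = 5000) {
  as.numeric(scale(qnorm(seq(0.01, 0.99, length.out = n))))
}
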