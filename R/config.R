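#' Simulation configuration for a synthetic biobank-style cohort
#'
#' Bundles every generative parameter of the synthetic cohort: variant panel
#' sizes, allele-frequency range, the fraction of each exposure's variance
#' explained by its unweighted genetic risk score, causal effects on the
#' outcome, exposure correlation induced through shared latent factors, the
#' loadings of an unmeasured confounder, optional pleiotropic (invalid)
#' instruments, genotype missingness, cohort-exclusion flag rates and the
#' outcome scale.
#'
#' Defaults mirror the statistical structure of the emulated study: three
#' exposures (neuroticism, education, physical activity) instrumented by
#' panels of 136, 70 and 22 variants whose scores explain 1.14%, 0.63% and
#' 0.03% of the exposure variance; causal effects (-0.31, 0.02, 0.08)
#' outcome units per exposure SD; an unmeasured confounder loading 0.3 on
#' each exposure and on the outcome; exclusion-flag rates equal to the
#' published attrition counts over a 500,000-person enrolment; and an
#' employment rate giving roughly 23% of participants a job-satisfaction
#' response.
#'
#' @param n_samples number of participants.
#' @param n_variants_per_trait integer vector of panel sizes for the
#'   neuroticism, education and physical-activity instruments.
#' @param maf_range range of effect-allele frequencies, within (0, 0.5].
#' @param target_r2 per-trait population fraction of exposure variance
#'   explained by its unweighted GRS, each in \[0, 1).
#' @param true_effects causal effect of each exposure on the latent outcome,
#'   outcome units per 1 SD of the measured exposure.
#' @param exposure_correlation 3x3 positive semi-definite correlation matrix
#'   of the exposures, or a single off-diagonal value.
#' @param confounder_exposures loadings of the unmeasured confounder on each
#'   exposure (SD units).
#' @param confounder_outcome loading of the confounder on the outcome.
#' @param n_invalid number of pleiotropic variants per panel with a direct
#'   effect on the outcome.
#' @param invalid_effect direct outcome effect per allele of each invalid
#'   variant.
#' @param missing_genotype_rate completely-at-random genotype missingness in
#'   \[0, 1).
#' @param flag_rates named probabilities of the six cohort-exclusion flags.
#' @param employment_rate probability a participant is employed (and so has
#'   a job-satisfaction response).
#' @param outcome_scale `"latent"` keeps the continuous outcome; `"likert6"`
#'   discretises it to the 1-6 questionnaire scale by fixed quantile
#'   cut-points.
#' @param outcome_sd SD of the outcome's Gaussian noise term.
#' @param n_centres number of assessment centres.
#' @param seed integer seed; all components draw from sub-streams derived
#'   from it.
#' @return an object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_samples = 500, seed = 1)
#' cfg$target_r2
#' @export
sim_config <- function(n_samples,
                       n_variants_per_trait = c(neuroticism = 136L,
                                                education = 70L,
                                                physical_activity = 22L),
                       maf_range = c(0.05, 0.5),
                       target_r2 = c(neuroticism = 0.0114,
                                     education = 0.0063,
                                     physical_activity = 0.0003),
                       true_effects = c(neuroticism = -0.31,
                                        education = 0.02,
                                        physical_activity = 0.08),
                       exposure_correlation = 0.3,
                       confounder_exposures = c(0.3, 0.3, 0.3),
                       confounder_outcome = 0.3,
                       n_invalid = c(0L, 0L, 0L),
                       invalid_effect = 0.1,
                       missing_genotype_rate = 0.02,
                       flag_rates = c(consent_withdrawn = 85 / 5e5,
                                      sex_mismatch = 373 / 5e5,
                                      related = 17284 / 5e5,
                                      non_british = 56261 / 5e5,
                                      icd10_mental_neuro = 25576 / 5e5,
                                      neuroticism_missing = 72294 / 5e5),
                       employment_rate = 73296 / 315536,
                       outcome_scale = c("latent", "likert6"),
                       outcome_sd = 1,
                       n_centres = 22L,
                       seed = 1L) {
  traits <- c("neuroticism", "education", "physical_activity")
  outcome_scale <- match.arg(outcome_scale)

  if (length(n_samples) != 1L || !is.finite(n_samples) || n_samples < 1)
    stop("n_samples must be a positive integer")
  n_variants_per_trait <- as.integer(n_variants_per_trait)
  if (length(n_variants_per_trait) != 3L || any(n_variants_per_trait < 1))
    stop("n_variants_per_trait must give a positive size for each of the three panels")
  names(n_variants_per_trait) <- traits
  if (length(maf_range) != 2L || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2])
    stop("maf_range must lie within (0, 0.5]")
  target_r2 <- as.numeric(target_r2)
  if (length(target_r2) != 3L || any(target_r2 < 0) || any(target_r2 >= 1))
    stop("target_r2 must be three fractions in [0, 1)")
  names(target_r2) <- traits
  true_effects <- as.numeric(true_effects)
  if (length(true_effects) != 3L) stop("true_effects must have length 3")
  names(true_effects) <- traits

  if (is.matrix(exposure_correlation)) {
    R <- exposure_correlation
  } else {
    R <- matrix(exposure_correlation, 3, 3)
    diag(R) <- 1
  }
  if (!isTRUE(all.equal(R, t(R))) || any(abs(diag(R) - 1) > 1e-12))
    stop("exposure_correlation must be a symmetric correlation matrix")
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("exposure_correlation must be positive semi-definite")
  dimnames(R) <- list(traits, traits)

  confounder_exposures <- as.numeric(confounder_exposures)
  if (length(confounder_exposures) != 3L)
    stop("confounder_exposures must have length 3")
  names(confounder_exposures) <- traits
  n_invalid <- as.integer(n_invalid)
  if (length(n_invalid) == 1L) n_invalid <- rep(n_invalid, 3L)
  if (any(n_invalid < 0) || any(n_invalid > n_variants_per_trait))
    stop("n_invalid must satisfy 0 <= n_invalid <= n_variants_per_trait per panel")
  names(n_invalid) <- traits
  if (missing_genotype_rate < 0 || missing_genotype_rate >= 1)
    stop("missing_genotype_rate must be in [0, 1)")
  flag_names <- c("consent_withdrawn", "sex_mismatch", "related", "non_british",
                  "icd10_mental_neuro", "neuroticism_missing")
  if (is.null(names(flag_rates))) names(flag_rates) <- flag_names
  if (!all(flag_names %in% names(flag_rates)))
    stop("flag_rates must name all six exclusion flags")
  flag_rates <- flag_rates[flag_names]
  if (any(flag_rates < 0) || any(flag_rates > 1))
    stop("flag_rates must be probabilities")
  if (employment_rate < 0 || employment_rate > 1)
    stop("employment_rate must be a probability")

  # residual covariance of the non-genetic exposure components must stay PSD
  # once the genetic share and the confounder loadings are carved out
  S <- R - tcrossprod(confounder_exposures)
  diag(S) <- 1 - target_r2 - confounder_exposures^2
  if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("infeasible configuration: target_r2, exposure_correlation and ",
         "confounder_exposures leave no valid residual covariance")

  structure(list(
    n_samples = as.integer(n_samples),
    n_variants_per_trait = n_variants_per_trait,
    maf_range = maf_range,
    target_r2 = target_r2,
    true_effects = true_effects,
    exposure_correlation = R,
    confounder_exposures = confounder_exposures,
    confounder_outcome = as.numeric(confounder_outcome),
    n_invalid = n_invalid,
    invalid_effect = as.numeric(invalid_effect),
    missing_genotype_rate = as.numeric(missing_genotype_rate),
    flag_rates = flag_rates,
    employment_rate = as.numeric(employment_rate),
    outcome_scale = outcome_scale,
    outcome_sd = as.numeric(outcome_sd),
    n_centres = as.integer(n_centres),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  samples: %d   seed: %d   outcome scale: %s\n",
              x$n_samples, x$seed, x$outcome_scale))
  cat(sprintf("  panels: %s\n",
              paste(sprintf("%s=%d", names(x$n_variants_per_trait),
                            x$n_variants_per_trait), collapse = "  ")))
  cat(sprintf("  GRS R2 targets: %s\n",
              paste(sprintf("%s=%.4f", names(x$target_r2), x$target_r2),
                    collapse = "  ")))
  cat(sprintf("  true effects: %s\n",
              paste(sprintf("%+.2f", x$true_effects), collapse = ", ")))
  invisible(x)
}

sim_traits <- function() c("neuroticism", "education", "physical_activity")
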