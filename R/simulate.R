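#' Simulate biallelic SNP genotypes in Hardy-Weinberg equilibrium
#'
#' Draws per-variant effect-allele frequencies uniformly from
#' `config$maf_range` and dosages from Binomial(2, eaf), then applies
#' completely-at-random missingness at `config$missing_genotype_rate`.
#' Allele pairs avoid the strand-ambiguous A/T and C/G combinations.
#'
#' The pre-missingness dosages are retained in the `"complete_dosages"`
#' attribute; downstream simulation stages treat them as the biological
#' truth, while analyses see only the observed (possibly missing) matrix.
#'
#' @param config a [sim_config()].
#' @return a [genotype_matrix()] with one panel per trait.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_samples
  m_per <- config$n_variants_per_trait
  m <- sum(m_per)
  traits <- sim_traits()
  with_seed(component_seed(config$seed, "genotypes"), {
    eaf <- runif(m, config$maf_range[1], config$maf_range[2])
    trait <- rep(traits, m_per)
    prefix <- rep(c("neu", "edu", "pa"), m_per)
    idx <- unlist(lapply(m_per, seq_len), use.names = FALSE)
    variant_id <- sprintf("%s_%03d", prefix, idx)

    # unambiguous allele pairs only (no A/T, no C/G)
    pairs <- rbind(c("A", "C"), c("A", "G"), c("C", "T"), c("G", "T"))
    pick <- pairs[sample.int(4L, m, replace = TRUE), , drop = FALSE]
    flip <- runif(m) < 0.5
    effect_allele <- ifelse(flip, pick[, 2], pick[, 1])
    other_allele <- ifelse(flip, pick[, 1], pick[, 2])

    complete <- matrix(rbinom(n * m, 2L, rep(eaf, each = n)), nrow = n, ncol = m)
    observed <- complete
    if (config$missing_genotype_rate > 0) {
      observed[runif(n * m) < config$missing_genotype_rate] <- NA
    }

    invalid <- logical(m)
    for (t in traits) {
      k <- config$n_invalid[[t]]
      if (k > 0) invalid[which(trait == t)[seq_len(k)]] <- TRUE
    }

    variants <- data.frame(variant_id = variant_id,
                           effect_allele = effect_allele,
                           other_allele = other_allele,
                           eaf = eaf,
                           trait = trait,
                           invalid = invalid,
                           stringsAsFactors = FALSE)
    g <- genotype_matrix(observed, variants,
                         sample_ids = sprintf("S%07d", seq_len(n)))
    dimnames(complete) <- dimnames(g$dosages)
    attr(g, "complete_dosages") <- complete
    g
  })
}

#' Simulate covariates and cohort-exclusion flags
#'
#' Age uniform on 37-73 years, sex Bernoulli(0.53) (1 = female), assessment
#' centre categorical, Townsend deprivation index and log-normal BMI, an
#' employment indicator, and the six exclusion flags each drawn Bernoulli at
#' its configured rate.
#'
#' @param config a [sim_config()].
#' @return data.frame with one row per sample.
#' @export
simulate_covariates_and_flags <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_samples
  with_seed(component_seed(config$seed, "covariates"), {
    out <- data.frame(
      sample_id = sprintf("S%07d", seq_len(n)),
      age = runif(n, 37, 73),
      sex = rbinom(n, 1L, 0.53),
      centre = factor(sprintf("centre_%02d",
                              sample.int(config$n_centres, n, replace = TRUE)),
                      levels = sprintf("centre_%02d", seq_len(config$n_centres))),
      tdi = rnorm(n, -1.3, 3),
      bmi = exp(rnorm(n, log(27), 0.15)),
      employed = rbinom(n, 1L, config$employment_rate) == 1L,
      stringsAsFactors = FALSE
    )
    for (f in names(config$flag_rates)) {
      out[[f]] <- rbinom(n, 1L, config$flag_rates[[f]]) == 1L
    }
    out
  })
}

#' Simulate exposures from genotypes
#'
#' Each latent exposure is the sum of a scaled unweighted-GRS signal, a
#' confounder loading, and correlated Gaussian residuals inducing the
#' configured exposure correlation; the genetic scaling is chosen so the
#' population R-squared of the exposure on its own unweighted GRS equals
#' `config$target_r2`. Latent traits are then mapped to questionnaire-style
#' observables: neuroticism to an integer 0-12 score, education to a highest
#' qualification category, and physical activity to weekly days/minutes of
#' walking, moderate and vigorous activity.
#'
#' @param genotypes a [genotype_matrix()] from [simulate_genotypes()].
#' @param config the same [sim_config()].
#' @return data.frame of raw phenotype fields plus `true_*` latent columns
#'   retained for testing.
#' @export
simulate_exposures <- function(genotypes, config) {
  stopifnot(inherits(config, "sim_config"))
  traits <- sim_traits()
  complete <- attr(genotypes, "complete_dosages")
  if (is.null(complete)) {
    # external genotypes: use observed dosages, mean-imputing missingness
    complete <- genotypes$dosages
    if (anyNA(complete)) {
      mu <- colMeans(complete, na.rm = TRUE)
      idx <- which(is.na(complete), arr.ind = TRUE)
      complete[idx] <- mu[idx[, 2]]
    }
  }
  n <- nrow(complete)

  with_seed(component_seed(config$seed, "exposures"), {
    # genetic component per trait, scaled to the target R2
    Xg <- matrix(0, n, 3, dimnames = list(NULL, traits))
    for (j in seq_along(traits)) {
      cols <- which(genotypes$variants$trait == traits[j])
      if (!length(cols)) stop("no variants for trait ", traits[j])
      eaf <- genotypes$variants$eaf[cols]
      var_g <- sum(2 * eaf * (1 - eaf))
      if (var_g <= 0)
        stop("target_r2 infeasible: panel for ", traits[j],
             " has zero dosage variance")
      a <- sqrt(config$target_r2[[j]] / var_g)
      grs <- rowSums(complete[, cols, drop = FALSE])
      Xg[, j] <- a * (grs - sum(2 * eaf))
    }

    U <- rnorm(n)
    # residual covariance: total correlation minus confounder cross-products
    S <- config$exposure_correlation - tcrossprod(config$confounder_exposures)
    diag(S) <- 1 - config$target_r2 - config$confounder_exposures^2
    ev <- eigen(S, symmetric = TRUE)
    if (min(ev$values) < -1e-8)
      stop("infeasible residual covariance for exposures")
    L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), 3)
    E <- matrix(rnorm(n * 3), n, 3) %*% t(L)

    X <- Xg + tcrossprod(U, config$confounder_exposures) + E
    colnames(X) <- traits

    # EPQ-N-style integer score 0-12: fixed monotone binning of the latent
    # trait at quantile cut-points (mean 4.13, SD 3.24 before truncation)
    neuroticism_score <- as.integer(pmin(12, pmax(0, round(4.13 + 3.24 * X[, 1]))))

    # highest qualification by quantile bands of the education latent
    edu_levels <- c("none", "cse_gcse", "a_level", "nvq_hnd",
                    "other_professional", "degree")
    edu_probs <- c(0.17, 0.25, 0.12, 0.18, 0.05, 0.23)
    cuts <- qnorm(cumsum(edu_probs)[-length(edu_probs)])
    qualification <- edu_levels[findInterval(X[, 2], cuts) + 1L]

    # physical activity: log-normal weekly MET-minutes target, split over
    # walking/moderate/vigorous at fixed shares (0.4/0.4/0.2); more active
    # people report more active days
    met_target <- exp(log(1200) + 1.0 * X[, 3])
    days <- pmax(1L, pmin(7L, as.integer(round(1 + 6 * pnorm(X[, 3])))))
    walk_min <- round(0.4 * met_target / (3.3 * days))
    mod_min <- round(0.4 * met_target / (4.0 * days))
    vig_min <- round(0.2 * met_target / (8.0 * days))

    data.frame(neuroticism_score = neuroticism_score,
               qualification = qualification,
               walk_days = days, walk_min = walk_min,
               mod_days = days, mod_min = mod_min,
               vig_days = days, vig_min = vig_min,
               true_confounder = U,
               true_neuroticism = X[, 1],
               true_education = X[, 2],
               true_physical_activity = X[, 3],
               stringsAsFactors = FALSE)
  })
}

#' Simulate the job-satisfaction outcome
#'
#' The latent outcome is a linear combination of the standardised *measured*
#' exposures (z of the 0-12 neuroticism score, z of mapped education years,
#' z of log(MET + 1)) at the configured `true_effects`, plus the confounder
#' loading, direct per-allele effects of any pleiotropic variants, and
#' Gaussian noise. Under `outcome_scale = "likert6"` the latent outcome is
#' discretised to 1-6 by fixed quantile cut-points; unemployed participants
#' get a missing outcome.
#'
#' Defining the causal effects on the measured scale makes `true_effects`
#' the exact estimand of the downstream TSLS/MVMR fits, which likewise see
#' only the measured z-scores.
#'
#' @param cohort data.frame containing the exposure fields from
#'   [simulate_exposures()] and an `employed` column.
#' @param genotypes the [genotype_matrix()] used to build the exposures.
#' @param config the same [sim_config()].
#' @return `cohort` with `job_satisfaction` and `true_outcome` columns.
#' @export
simulate_outcome <- function(cohort, genotypes, config) {
  stopifnot(inherits(config, "sim_config"))
  if (!all(c("neuroticism_score", "qualification", "walk_days") %in% names(cohort)))
    stop("exposures must be simulated before the outcome")
  n <- nrow(cohort)

  z1 <- standardize(cohort$neuroticism_score)
  years <- map_education_years(cohort$qualification)
  z2 <- standardize(years)
  met <- compute_met_score(cohort$walk_days, cohort$walk_min,
                           cohort$mod_days, cohort$mod_min,
                           cohort$vig_days, cohort$vig_min)
  z3 <- standardize(log(met + 1))
  Z <- cbind(z1, z2, z3)

  with_seed(component_seed(config$seed, "outcome"), {
    y <- drop(Z %*% config$true_effects) +
      config$confounder_outcome * cohort$true_confounder

    inv <- which(genotypes$variants$invalid %||% rep(FALSE, ncol(genotypes$dosages)))
    if (length(inv)) {
      complete <- attr(genotypes, "complete_dosages")
      if (is.null(complete)) complete <- genotypes$dosages
      d <- complete[, inv, drop = FALSE]
      eaf <- genotypes$variants$eaf[inv]
      y <- y + drop(sweep(d, 2, 2 * eaf) %*% rep(config$invalid_effect, length(inv)))
    }

    y <- y + rnorm(n, 0, config$outcome_sd)

    js <- if (config$outcome_scale == "likert6") {
      # skewed towards satisfaction, as in the questionnaire
      cuts <- quantile(y, c(0.02, 0.05, 0.13, 0.30, 0.80), names = FALSE)
      as.numeric(findInterval(y, cuts) + 1L)
    } else {
      y
    }
    js[!cohort$employed] <- NA_real_

    cohort$true_outcome <- y
    cohort$job_satisfaction <- js
    attr(cohort, "outcome_scale") <- config$outcome_scale
    cohort
  })
}

#' Simulate a complete synthetic cohort
#'
#' Orchestrates [simulate_genotypes()], [simulate_covariates_and_flags()],
#' [simulate_exposures()] and [simulate_outcome()], and assembles the
#' instrument-definition table. Participants flagged as missing neuroticism
#' have their raw score blanked to mirror the questionnaire.
#'
#' A fixed seed yields a bit-identical cohort on repeated calls.
#'
#' @param config a [sim_config()].
#' @return list with elements `genotypes` (a [genotype_matrix()]), `cohort`
#'   (data.frame) and `instruments` (variant/effect-allele/trait table).
#' @examples
#' sim <- simulate_cohort(sim_config(n_samples = 300, seed = 7))
#' head(sim$cohort[, c("age", "sex", "neuroticism_score", "job_satisfaction")])
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  genotypes <- simulate_genotypes(config)
  covs <- simulate_covariates_and_flags(config)
  expo <- simulate_exposures(genotypes, config)
  cohort <- cbind(covs, expo)
  cohort <- simulate_outcome(cohort, genotypes, config)
  cohort$neuroticism_score[cohort$neuroticism_missing] <- NA_integer_
  instruments <- genotypes$variants[, c("variant_id", "effect_allele",
                                        "other_allele", "trait")]
  list(genotypes = genotypes, cohort = cohort, instruments = instruments)
}
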