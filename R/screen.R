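#' Per-variant instrument-validity screen
#'
#' For every variant of a trait panel, two least-squares regressions are
#' fitted: the trait on the variant dosage adjusting for age and sex, and
#' job satisfaction on the dosage adjusting for the trait plus the analysis
#' covariates (age, sex, centre, deprivation index by default; set
#' `adjust = "minimal"` for age/sex only). A variant is retained only if it
#' shows nominal association with its trait (p < `alpha_trait`) and no
#' nominal association with the outcome (p >= `alpha_outcome`).
#'
#' The per-variant regressions are computed by partialling the covariates
#' out of the dosage, trait and outcome (Frisch-Waugh), which is
#' algebraically identical to the full least-squares fits but lets a whole
#' panel be screened with a handful of matrix operations. Missing dosages
#' are mean-imputed for the screen.
#'
#' @param genotypes an aligned [genotype_matrix()].
#' @param cohort derived cohort (see [derive_phenotypes()]); only rows with
#'   `analysis_eligible` are used.
#' @param instruments instrument table.
#' @param trait_columns named map from trait label to the cohort column
#'   holding the measured trait.
#' @param outcome_column outcome column name.
#' @param adjust `"full"` (age, sex, centre, TDI) or `"minimal"` (age, sex)
#'   covariates in the outcome screen.
#' @param alpha_trait,alpha_outcome nominal significance levels.
#' @return data.frame of class `screening_result`: one row per variant with
#'   `p_trait`, `p_outcome`, `decision` and a reason code
#'   (`weak_with_trait`, `outcome_associated` or `retained`).
#' @export
screen_instruments <- function(genotypes, cohort, instruments,
                               trait_columns = c(neuroticism = "z_neuroticism",
                                                 education = "z_education",
                                                 physical_activity = "z_met"),
                               outcome_column = "job_satisfaction",
                               adjust = c("full", "minimal"),
                               alpha_trait = 0.05, alpha_outcome = 0.05) {
  adjust <- match.arg(adjust)
  elig <- cohort$analysis_eligible %||% rep(TRUE, nrow(cohort))
  rows <- list()
  for (trait in unique(instruments$trait)) {
    tc <- trait_columns[[trait]]
    if (is.null(tc)) stop("no trait column mapped for '", trait, "'")
    panel <- intersect(instruments$variant_id[instruments$trait == trait],
                       genotypes$variants$variant_id)
    if (!length(panel)) next
    D <- genotypes$dosages[, panel, drop = FALSE]
    if (anyNA(D)) {
      mu <- colMeans(D, na.rm = TRUE)
      idx <- which(is.na(D), arr.ind = TRUE)
      D[idx] <- mu[idx[, 2]]
    }

    # trait model: trait ~ dosage + age + sex
    C1 <- cbind(1, cohort$age, cohort$sex)
    ok1 <- elig & complete.cases(C1, cohort[[tc]])
    if (sum(ok1) < 10L) stop("fewer than 10 analysis rows for trait screen")
    p_trait <- partial_regression_p(D[ok1, , drop = FALSE],
                                    cohort[[tc]][ok1],
                                    C1[ok1, , drop = FALSE])

    # outcome model: outcome ~ dosage + trait + covariates
    C2 <- if (adjust == "full") {
      cbind(1, cohort$age, cohort$sex,
            model.matrix(~ centre, cohort)[, -1, drop = FALSE],
            cohort$tdi, cohort[[tc]])
    } else {
      cbind(1, cohort$age, cohort$sex, cohort[[tc]])
    }
    ok2 <- elig & complete.cases(C2, cohort[[outcome_column]])
    if (sum(ok2) < 10L) stop("fewer than 10 analysis rows for outcome screen")
    p_outcome <- partial_regression_p(D[ok2, , drop = FALSE],
                                      cohort[[outcome_column]][ok2],
                                      C2[ok2, , drop = FALSE])

    zero_var <- apply(D[ok1, , drop = FALSE], 2, var) == 0
    decision <- !is.na(p_trait) & p_trait < alpha_trait &
      !is.na(p_outcome) & p_outcome >= alpha_outcome & !zero_var
    reason <- ifelse(zero_var | is.na(p_trait) | p_trait >= alpha_trait,
                     "weak_with_trait",
                     ifelse(!is.na(p_outcome) & p_outcome < alpha_outcome,
                            "outcome_associated", "retained"))
    rows[[trait]] <- data.frame(variant_id = panel,
                                trait = trait,
                                p_trait = unname(p_trait),
                                p_outcome = unname(p_outcome),
                                decision = ifelse(decision, "retained", "excluded"),
                                reason = reason,
                                stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("screening_result", "data.frame")
  out
}

# two-sided p-values for each column of D in y ~ D[,j] + C, via the
# Frisch-Waugh partialled regression (exact least-squares equivalence)
partial_regression_p <- function(D, y, C) {
  qC <- qr(C)
  ry <- qr.resid(qC, y)
  RD <- qr.resid(qC, D)
  ss_d <- colSums(RD^2)
  slope <- colSums(RD * ry) / ss_d
  rss <- sum(ry^2) - slope^2 * ss_d
  dof <- length(y) - qC$rank - 1L
  se <- sqrt(pmax(rss, 0) / dof / ss_d)
  p <- 2 * pt(-abs(slope / se), df = dof)
  p[ss_d <= 1e-12] <- NA_real_
  p
}

#' Sensitivity genetic risk score from screened instruments
#'
#' Rebuilds the unweighted GRS for a trait using only the variants the
#' validity screen retained.
#'
#' @param screening a `screening_result` from [screen_instruments()].
#' @param genotypes an aligned [genotype_matrix()].
#' @param instruments instrument table.
#' @param trait trait label.
#' @param ... passed to [compute_unweighted_grs()].
#' @return a `grs_result` with `n_retained`/`n_excluded` counts attached.
#' @export
build_sensitivity_grs <- function(screening, genotypes, instruments, trait, ...) {
  sub <- screening[screening$trait == trait, , drop = FALSE]
  kept <- sub$variant_id[sub$decision == "retained"]
  if (!length(kept))
    stop("no variants retained by the screen for trait '", trait, "'")
  out <- compute_unweighted_grs(genotypes,
                                instruments[instruments$variant_id %in% kept, ,
                                            drop = FALSE],
                                trait, ...)
  out$n_retained <- length(kept)
  out$n_excluded <- nrow(sub) - length(kept)
  out
}
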