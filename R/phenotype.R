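#' Apply cohort exclusion criteria
#'
#' Marks rows ineligible when any of the six exclusion flags is set, in the
#' listed order: consent withdrawal, sex mismatch, genetic relatedness,
#' non-British or missing ethnicity, ICD-10 mental/behavioural or
#' neurological history, and missing neuroticism score. Attrition is
#' reported with each removed participant attributed to the earliest listed
#' criterion that flags them.
#'
#' @param cohort data.frame containing the six logical flag columns.
#' @param flags character vector naming the flag columns, in exclusion
#'   order.
#' @return `cohort` with a logical `analysis_eligible` column and an
#'   `"attrition"` attribute (data.frame of per-criterion removal counts).
#' @export
apply_cohort_exclusions <- function(cohort,
                                    flags = c("consent_withdrawn",
                                              "sex_mismatch",
                                              "related",
                                              "non_british",
                                              "icd10_mental_neuro",
                                              "neuroticism_missing")) {
  missing_cols <- setdiff(flags, names(cohort))
  if (length(missing_cols))
    stop("missing flag column(s): ", paste(missing_cols, collapse = ", "))
  flag_mat <- vapply(flags, function(f) as.logical(cohort[[f]]),
                     logical(nrow(cohort)))
  flag_mat <- matrix(flag_mat, nrow = nrow(cohort),
                     dimnames = list(NULL, flags))
  already <- rep(FALSE, nrow(cohort))
  removed <- integer(length(flags))
  for (i in seq_along(flags)) {
    hit <- flag_mat[, i] & !already
    removed[i] <- sum(hit)
    already <- already | flag_mat[, i]
  }
  cohort$analysis_eligible <- !already
  attr(cohort, "attrition") <- data.frame(
    criterion = flags,
    n_removed = removed,
    n_remaining = nrow(cohort) - cumsum(removed),
    stringsAsFactors = FALSE
  )
  cohort
}

#' Set extreme activity durations to missing
#'
#' For each duration variable, values whose z-score (computed on the raw,
#' untransformed durations over non-missing rows) lies strictly outside
#' +-3.29 are set missing. The sample is retained for other analyses. The
#' rule is applied in a single pass; a zero-variance column yields no
#' exclusions.
#'
#' @param cohort data.frame with the duration columns.
#' @param cols duration columns to screen.
#' @param threshold absolute z-score cut-off.
#' @return `cohort` with outliers blanked and an `"outlier_removals"`
#'   attribute of per-column counts.
#' @export
exclude_duration_outliers <- function(cohort,
                                      cols = c("walk_min", "mod_min", "vig_min"),
                                      threshold = 3.29) {
  removed <- setNames(integer(length(cols)), cols)
  for (cl in cols) {
    x <- cohort[[cl]]
    ok <- !is.na(x)
    if (sum(ok) < 2L) next
    s <- sd(x[ok])
    if (s == 0) {
      message("no variance in '", cl, "'; no outliers excluded")
      next
    }
    z <- (x - mean(x[ok])) / s
    out <- ok & abs(z) > threshold
    removed[cl] <- sum(out)
    cohort[[cl]][out] <- NA
  }
  attr(cohort, "outlier_removals") <- removed
  cohort
}

#' Weekly MET-minutes from the short-form activity questionnaire
#'
#' `met = walk_days * walk_min * 3.3 + mod_days * mod_min * 4.0 +
#' vig_days * vig_min * 8.0`, where days count days per week with at least
#' a 10-minute bout of that activity. Any missing input gives a missing
#' score.
#'
#' @param walk_days,mod_days,vig_days days per week (0-7).
#' @param walk_min,mod_min,vig_min typical daily duration in minutes.
#' @return numeric vector of MET-minutes per week.
#' @examples
#' compute_met_score(7, 30, 5, 30, 2, 20)  # 693 + 600 + 320 = 1613
#' @export
compute_met_score <- function(walk_days, walk_min, mod_days, mod_min,
                              vig_days, vig_min) {
  args <- list(walk_days, walk_min, mod_days, mod_min, vig_days, vig_min)
  n <- max(lengths(args))
  args <- lapply(args, rep_len, n)
  days <- args[c(1, 3, 5)]
  mins <- args[c(2, 4, 6)]
  for (d in days) {
    if (any(d < 0 | d > 7, na.rm = TRUE))
      stop("days per week must lie in [0, 7]")
  }
  for (m in mins) {
    if (any(m < 0, na.rm = TRUE)) stop("durations must be non-negative")
  }
  args[[1]] * args[[2]] * 3.3 +
    args[[3]] * args[[4]] * 4.0 +
    args[[5]] * args[[6]] * 8.0
}

#' Default qualification-to-leaving-age mapping
#'
#' Assigns the age at which a participant left full-time education from the
#' highest reported qualification; ages span 15 (no qualification) to 21
#' (degree). The mapping is fully overridable.
#'
#' @return named numeric vector, category -> years.
#' @export
default_education_mapping <- function() {
  c(none = 15, cse_gcse = 16, o_level = 16, gcse = 16,
    a_level = 18, nvq_hnd = 19, other_professional = 20, degree = 21)
}

#' Map qualification categories to education leaving age
#'
#' @param category character vector of qualification categories.
#' @param mapping named vector from [default_education_mapping()] or a
#'   user-supplied override; all ages must lie in \[15, 21\].
#' @return numeric years; unknown categories give NA with a warning.
#' @export
map_education_years <- function(category, mapping = default_education_mapping()) {
  if (any(mapping < 15 | mapping > 21))
    stop("education leaving ages must lie in [15, 21]")
  out <- unname(mapping[as.character(category)])
  unknown <- !is.na(category) & is.na(out)
  if (any(unknown))
    warning("unknown qualification categories set to missing: ",
            paste(unique(category[unknown]), collapse = ", "))
  out
}

#' Recode the job-satisfaction response
#'
#' Unemployed participants and "do not know"/"prefer not to answer" codes
#' become missing. On the 1-6 questionnaire scale higher values mean higher
#' satisfaction; values outside 1-6 that are not recognised missing codes
#' are an error. Continuous (latent-scale) outcomes are passed through with
#' only the unemployment rule applied.
#'
#' @param raw numeric 1-6 responses, or character including missing codes,
#'   or a continuous latent outcome.
#' @param employed logical (or 0/1) employment indicator.
#' @param missing_codes responses treated as missing.
#' @param scale `"likert6"` validates the 1-6 range; `"latent"` passes
#'   continuous values through.
#' @return numeric vector with missing where unemployed or uninformative.
#' @export
recode_job_satisfaction <- function(raw, employed,
                                    missing_codes = c("do not know",
                                                      "prefer not to answer"),
                                    scale = c("likert6", "latent")) {
  scale <- match.arg(scale)
  if (is.character(raw)) {
    code <- tolower(trimws(raw)) %in% tolower(missing_codes)
    out <- suppressWarnings(as.numeric(raw))
    if (any(!code & is.na(out) & !is.na(raw)))
      stop("unrecognised job-satisfaction response: ",
           paste(unique(raw[!code & is.na(out) & !is.na(raw)]), collapse = ", "))
    out[code] <- NA_real_
  } else {
    out <- as.numeric(raw)
    out[out %in% suppressWarnings(as.numeric(missing_codes))] <- NA_real_
  }
  if (scale == "likert6") {
    bad <- !is.na(out) & (out < 1 | out > 6 | out != round(out))
    if (any(bad))
      stop("job-satisfaction responses outside 1-6: ",
           paste(unique(out[bad]), collapse = ", "))
  }
  out[!as.logical(employed)] <- NA_real_
  out
}

#' Standardise to zero mean and unit SD
#'
#' `(x - mean) / sd` over non-missing values, with the n-1 sample SD;
#' missing values stay missing.
#'
#' @param x numeric vector with at least two distinct non-missing values.
#' @return z-scored vector.
#' @export
standardize <- function(x) {
  ok <- !is.na(x)
  if (sum(ok) < 2L) stop("need at least 2 non-missing values to standardise")
  s <- sd(x[ok])
  if (s == 0) stop("cannot standardise a constant vector")
  (x - mean(x[ok])) / s
}

#' Derive analysis variables from raw questionnaire fields
#'
#' Applies the cohort exclusions and the duration-outlier rule, computes the
#' MET score, maps education to leaving age, recodes job satisfaction, log
#' transforms MET (as log(MET + 1), so zero activity is representable) and
#' BMI, and z-scores neuroticism, education and log-MET over the eligible
#' analysis sample.
#'
#' @param cohort raw cohort data.frame (e.g. from [simulate_cohort()]).
#' @param mapping education mapping, see [map_education_years()].
#' @param exclusions apply the six-flag exclusion cascade.
#' @return `cohort` with derived columns `met_score`, `log_met`, `log_bmi`,
#'   `education_years`, `z_neuroticism`, `z_education`, `z_met`,
#'   `job_satisfaction` and `analysis_eligible`; attrition and outlier
#'   counts attached as attributes.
#' @export
derive_phenotypes <- function(cohort, mapping = default_education_mapping(),
                              exclusions = TRUE) {
  if (exclusions) {
    cohort <- apply_cohort_exclusions(cohort)
  } else if (is.null(cohort$analysis_eligible)) {
    cohort$analysis_eligible <- TRUE
  }
  attrition <- attr(cohort, "attrition")
  cohort <- exclude_duration_outliers(cohort)
  outliers <- attr(cohort, "outlier_removals")

  cohort$met_score <- compute_met_score(cohort$walk_days, cohort$walk_min,
                                        cohort$mod_days, cohort$mod_min,
                                        cohort$vig_days, cohort$vig_min)
  cohort$log_met <- log(cohort$met_score + 1)
  cohort$log_bmi <- log(cohort$bmi)
  cohort$education_years <- map_education_years(cohort$qualification, mapping)
  outcome_scale <- attr(cohort, "outcome_scale") %||% "likert6"
  cohort$job_satisfaction <- recode_job_satisfaction(cohort$job_satisfaction,
                                                     cohort$employed,
                                                     scale = outcome_scale)

  elig <- cohort$analysis_eligible
  zcol <- function(x) {
    z <- rep(NA_real_, length(x))
    z[elig] <- standardize(x[elig])
    z
  }
  cohort$z_neuroticism <- zcol(cohort$neuroticism_score)
  cohort$z_education <- zcol(cohort$education_years)
  cohort$z_met <- zcol(cohort$log_met)

  attr(cohort, "attrition") <- attrition
  attr(cohort, "outlier_removals") <- outliers
  cohort
}
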