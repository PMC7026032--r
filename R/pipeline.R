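#' Read a pipeline run configuration
#'
#' The configuration is YAML with top-level keys `seed`, `simulation` (a
#' [sim_config()] argument list for self-contained runs) or `paths`
#' (genotypes/variants/cohort/instruments for file-based runs), `model`
#' (covariates, `bmi_adjust`, instrumenting mode), `screening` (logical)
#' and `power_beta`.
#'
#' @param path YAML file path.
#' @return a named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  as_run_config(cfg)
}

#' @rdname read_run_config
#' @param config a named list with the same structure as the YAML file.
#' @export
as_run_config <- function(config) {
  if (is.null(config$simulation) && is.null(config$paths))
    stop("config error: either 'simulation' or 'paths' must be present")
  config$seed <- as.integer(config$seed %||% 1L)
  config$screening <- isTRUE(config$screening %||% TRUE)
  config$power_beta <- config$power_beta %||% 0.30
  model <- config$model %||% list()
  model$covariates <- model$covariates %||% c("age", "sex", "centre", "tdi")
  model$bmi_adjust <- isTRUE(model$bmi_adjust %||% FALSE)
  model$instrumenting <- model$instrumenting %||% "own"
  config$model <- model
  class(config) <- "run_config"
  config
}

pipeline_covariates <- function(config) {
  covs <- config$model$covariates
  if (config$model$bmi_adjust) covs <- union(covs, "log_bmi")
  covs
}

stage_header <- function(config_hash, seed) {
  sprintf("# grsmr\tconfig_hash=%s\tseed=%d", config_hash, seed)
}

write_stage_tsv <- function(df, path, config_hash, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(stage_header(config_hash, seed), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_stage_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  hash <- sub(".*config_hash=([^\t]+).*", "\\1", first)
  out <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  attr(out, "config_hash") <- hash
  out
}

fit_row <- function(fit, model, trait, term, covariates) {
  co <- fit$coefficients
  co <- co[co$term == term, , drop = FALSE]
  fs <- fit$diagnostics$first_stage_f
  cf <- fit$diagnostics$conditional_f
  data.frame(model = model, trait = trait,
             estimate = co$estimate, se = co$se,
             ci_low = co$ci_low, ci_high = co$ci_high, p = co$p,
             n = fit$n,
             f_statistic = if (!is.null(fs) && term %in% names(fs)) fs[[term]] else NA_real_,
             conditional_f = if (!is.null(cf) && term %in% names(cf)) cf[[term]] else NA_real_,
             covariates = paste(covariates, collapse = "+"),
             stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or load) -> derive -> GRS -> observational ->
#' univariable MR -> multivariable MR -> instrument screening + sensitivity
#' re-fit -> power, writing one TSV per stage plus a consolidated results
#' table, a machine-readable manifest and a plain-text report into
#' `out_dir`. Every output carries the configuration hash and seed, and a
#' re-run with the same configuration is byte-identical.
#'
#' @param config a `run_config` (see [read_run_config()]), a path to a YAML
#'   file, or a plain list.
#' @param out_dir output directory (created if needed); defaults to
#'   `config$out`.
#' @return the output directory, invisibly.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config")) config <- as_run_config(config)
  out_dir <- out_dir %||% config$out %||% stop("config error: no output directory")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  # hash the scientific configuration only (not where it is written)
  hashed <- unclass(config)
  hashed$out <- NULL
  hash <- rlang::hash(hashed[sort(names(hashed))])
  covs <- pipeline_covariates(config)
  traits <- sim_traits()
  trait_cols <- c(neuroticism = "z_neuroticism", education = "z_education",
                  physical_activity = "z_met")
  grs_cols <- paste0("grs_", traits)

  ## stage: inputs -------------------------------------------------------
  inputs <- tryCatch({
    if (!is.null(config$simulation)) {
      sim_args <- config$simulation
      sim_args$seed <- sim_args$seed %||% config$seed
      sim <- simulate_cohort(do.call(sim_config, sim_args))
      write_genotypes_tsv(sim$genotypes, file.path(out_dir, "genotypes.tsv"),
                          file.path(out_dir, "variants.tsv"))
      write_instruments(sim$instruments, file.path(out_dir, "instruments.tsv"))
      write_cohort_tsv(sim$cohort, file.path(out_dir, "cohort_raw.tsv"))
      sim
    } else {
      p <- config$paths
      g <- read_genotypes(p$genotypes,
                          format = p$format %||% "tsv",
                          variant_file = p$variants)
      cohort <- read_cohort_tsv(p$cohort)
      list(genotypes = g, cohort = cohort,
           instruments = read_instruments(p$instruments))
    }
  }, error = function(e) stop_stage("inputs", e))

  ## stage: phenotype derivation ----------------------------------------
  cohort <- tryCatch({
    dv <- derive_phenotypes(inputs$cohort)
    att <- attr(dv, "attrition")
    if (!is.null(att)) {
      write_stage_tsv(att, file.path(out_dir, "attrition.tsv"), hash, config$seed)
      for (i in seq_len(nrow(att)))
        message(sprintf("excluded %d (%s); %d remaining",
                        att$n_removed[i], att$criterion[i], att$n_remaining[i]))
    }
    dv
  }, error = function(e) stop_stage("derive", e))

  ## stage: genetic risk scores -----------------------------------------
  grs_tab <- tryCatch({
    g <- variant_qc(inputs$genotypes)
    removed <- attr(g, "removed_variants")
    if (nrow(removed))
      message(sprintf("variant QC removed %d variant(s)", nrow(removed)))
    g <- align_effect_alleles(g, inputs$instruments)
    rows <- list()
    for (t in traits) {
      grs <- compute_unweighted_grs(g, inputs$instruments, t)
      cohort[[paste0("grs_", t)]] <- unname(grs$score)
      ve <- variance_explained(grs$score[cohort$analysis_eligible],
                               cohort[[trait_cols[[t]]]][cohort$analysis_eligible],
                               cohort$age[cohort$analysis_eligible],
                               cohort$sex[cohort$analysis_eligible])
      rows[[t]] <- data.frame(trait = t, n_variants = grs$n_variants_used,
                              beta = ve$beta, se = ve$se, p = ve$p,
                              variance_explained_pct = 100 * ve$r2,
                              n = ve$n, stringsAsFactors = FALSE)
    }
    aligned_genotypes <- g
    tab <- do.call(rbind, rows)
    write_stage_tsv(tab, file.path(out_dir, "grs.tsv"), hash, config$seed)
    list(tab = tab, genotypes = aligned_genotypes)
  }, error = function(e) stop_stage("grs", e))

  results <- list()

  ## stage: observational -----------------------------------------------
  tryCatch({
    for (t in traits) {
      sp <- model_spec("job_satisfaction", trait_cols[[t]], covariates = covs)
      results[[paste0("obs_uni_", t)]] <-
        fit_row(fit_ols(sp, cohort), "observational_univariable", t,
                trait_cols[[t]], covs)
    }
    spm <- model_spec("job_satisfaction", unname(trait_cols), covariates = covs)
    fitm <- fit_ols(spm, cohort)
    for (t in traits)
      results[[paste0("obs_multi_", t)]] <-
        fit_row(fitm, "observational_multivariable", t, trait_cols[[t]], covs)
  }, error = function(e) stop_stage("observational", e))

  ## stage: univariable MR ----------------------------------------------
  tryCatch({
    for (t in traits) {
      sp <- model_spec("job_satisfaction", trait_cols[[t]],
                       instruments = paste0("grs_", t),
                       covariates = covs, estimator = "tsls")
      results[[paste0("mr_uni_", t)]] <-
        fit_row(fit_tsls(sp, cohort), "mr_univariable", t, trait_cols[[t]], covs)
    }
  }, error = function(e) stop_stage("mr", e))

  ## stage: multivariable MR --------------------------------------------
  tryCatch({
    spm <- model_spec("job_satisfaction", unname(trait_cols),
                      instruments = grs_cols, covariates = covs,
                      estimator = "mvmr",
                      instrumenting = config$model$instrumenting)
    fitm <- fit_mvmr(spm, cohort)
    for (t in traits)
      results[[paste0("mvmr_", t)]] <-
        fit_row(fitm, "mvmr", t, trait_cols[[t]], covs)
  }, error = function(e) stop_stage("mvmr", e))

  ## stage: screening + sensitivity refit -------------------------------
  screening_tab <- NULL
  sensitivity <- NULL
  if (config$screening) {
    tryCatch({
      screening_tab <- screen_instruments(grs_tab$genotypes, cohort,
                                          inputs$instruments,
                                          trait_columns = trait_cols)
      write_stage_tsv(screening_tab, file.path(out_dir, "screening.tsv"),
                      hash, config$seed)
      sens_rows <- list()
      for (t in traits) {
        sg <- build_sensitivity_grs(screening_tab, grs_tab$genotypes,
                                    inputs$instruments, t)
        cohort[[paste0("sens_grs_", t)]] <- unname(sg$score)
        message(sprintf("sensitivity GRS for %s: %d retained, %d excluded",
                        t, sg$n_retained, sg$n_excluded))
      }
      for (t in traits) {
        sp <- model_spec("job_satisfaction", trait_cols[[t]],
                         instruments = paste0("sens_grs_", t),
                         covariates = covs, estimator = "tsls")
        sens_rows[[paste0("uni_", t)]] <-
          fit_row(fit_tsls(sp, cohort), "sensitivity_mr_univariable", t,
                  trait_cols[[t]], covs)
      }
      spm <- model_spec("job_satisfaction", unname(trait_cols),
                        instruments = paste0("sens_grs_", traits),
                        covariates = covs, estimator = "mvmr",
                        instrumenting = config$model$instrumenting)
      fitm <- fit_mvmr(spm, cohort)
      for (t in traits)
        sens_rows[[paste0("mvmr_", t)]] <-
          fit_row(fitm, "sensitivity_mvmr", t, trait_cols[[t]], covs)
      sensitivity <- do.call(rbind, sens_rows)
      rownames(sensitivity) <- NULL
      write_stage_tsv(sensitivity, file.path(out_dir, "sensitivity.tsv"),
                      hash, config$seed)
    }, error = function(e) stop_stage("screening", e))
  }

  ## stage: power --------------------------------------------------------
  power_tab <- tryCatch({
    rows <- lapply(traits, function(t) {
      n_t <- sum(complete.cases(cohort$job_satisfaction[cohort$analysis_eligible],
                                cohort[[trait_cols[[t]]]][cohort$analysis_eligible]))
      r2 <- grs_tab$tab$variance_explained_pct[grs_tab$tab$trait == t] / 100
      r2 <- max(r2, 1e-8)
      data.frame(trait = t, n = n_t, r2_gx = r2,
                 beta_std = config$power_beta,
                 ncp = mr_ncp(n_t, r2, config$power_beta),
                 power = mr_power(n_t, r2, config$power_beta),
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    write_stage_tsv(tab, file.path(out_dir, "power.tsv"), hash, config$seed)
    tab
  }, error = function(e) stop_stage("power", e))

  ## consolidated results + manifest -------------------------------------
  res <- do.call(rbind, results)
  rownames(res) <- NULL
  write_stage_tsv(res, file.path(out_dir, "results.tsv"), hash, config$seed)
  write_stage_tsv(cohort[, !vapply(cohort, is.list, logical(1))],
                  file.path(out_dir, "cohort_derived.tsv"), hash, config$seed)
  manifest <- list(package = "grsmr",
                   version = as.character(packageVersion("grsmr")),
                   seed = config$seed,
                   config_hash = hash,
                   screening = config$screening,
                   bmi_adjust = config$model$bmi_adjust,
                   covariates = covs,
                   stages = c("inputs", "derive", "grs", "observational",
                              "mr", "mvmr",
                              if (config$screening) "screening", "power"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  make_report(out_dir)
  invisible(out_dir)
}

#' Assemble the plain-text run report
#'
#' Renders estimate (95% CI, p) for every model and trait, first-stage and
#' conditional F (flagging weak instruments, F < 10), screening counts and
#' the power calculation from a completed run directory. Stage outputs with
#' mismatched configuration hashes are an error.
#'
#' @param run_dir directory written by [run_pipeline()].
#' @return the report lines, invisibly; also written to `report.txt`.
#' @export
make_report <- function(run_dir) {
  need <- c("results.tsv", "grs.tsv", "power.tsv")
  paths <- file.path(run_dir, need)
  if (!all(file.exists(paths)))
    stop("missing stage output(s): ",
         paste(need[!file.exists(paths)], collapse = ", "))
  res <- read_stage_tsv(file.path(run_dir, "results.tsv"))
  grs <- read_stage_tsv(file.path(run_dir, "grs.tsv"))
  pow <- read_stage_tsv(file.path(run_dir, "power.tsv"))
  hashes <- c(attr(res, "config_hash"), attr(grs, "config_hash"),
              attr(pow, "config_hash"))
  screening_path <- file.path(run_dir, "screening.tsv")
  sens_path <- file.path(run_dir, "sensitivity.tsv")
  if (file.exists(screening_path)) {
    scr <- read_stage_tsv(screening_path)
    hashes <- c(hashes, attr(scr, "config_hash"))
  }
  if (length(unique(hashes)) != 1L)
    stop("config-hash mismatch across stage outputs; mixed run directory?")

  fmt_row <- function(r) {
    flag <- if (!is.na(r$f_statistic) && r$f_statistic < 10) "  ** WEAK INSTRUMENT (F<10)" else ""
    sprintf("  %-28s %-18s %7.3f (%7.3f to %7.3f)  p=%-9.3g F=%-7s swF=%-7s%s",
            r$model, r$trait, r$estimate, r$ci_low, r$ci_high, r$p,
            ifelse(is.na(r$f_statistic), "-", sprintf("%.1f", r$f_statistic)),
            ifelse(is.na(r$conditional_f), "-", sprintf("%.1f", r$conditional_f)),
            flag)
  }

  lines <- c("grsmr run report",
             strrep("=", 70),
             "",
             "Genetic risk scores (incremental R2 over age + sex):",
             sprintf("  %-18s %3d variants  beta=%8.4f  se=%7.4f  R2=%6.3f%%",
                     grs$trait, grs$n_variants, grs$beta, grs$se,
                     grs$variance_explained_pct),
             "",
             "Estimates (95% CI) per 1 SD of exposure:",
             vapply(seq_len(nrow(res)), function(i) fmt_row(res[i, ]), character(1)),
             "")
  if (file.exists(screening_path)) {
    scr <- read_stage_tsv(screening_path)
    counts <- stats::aggregate(decision ~ trait, scr,
                               function(d) sum(d == "retained"))
    tot <- table(scr$trait)
    lines <- c(lines, "Instrument validity screen:",
               sprintf("  %-18s retained %d of %d",
                       counts$trait, counts$decision,
                       as.integer(tot[counts$trait])))
    if (file.exists(sens_path)) {
      sens <- read_stage_tsv(sens_path)
      lines <- c(lines, "", "Sensitivity estimates (screened GRS):",
                 vapply(seq_len(nrow(sens)), function(i) fmt_row(sens[i, ]),
                        character(1)))
    }
  } else {
    lines <- c(lines, "Instrument validity screen: skipped")
  }
  lines <- c(lines, "",
             "Analytic power (two-sided alpha 0.05):",
             sprintf("  %-18s n=%-7d R2=%7.4f%%  beta=%.2f  NCP=%8.2f  power=%.4f (%.0f%%)",
                     pow$trait, pow$n, 100 * pow$r2_gx, pow$beta_std, pow$ncp,
                     pow$power, round(100 * pow$power)))
  writeLines(lines, file.path(run_dir, "report.txt"))
  invisible(lines)
}
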