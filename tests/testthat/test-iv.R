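# six-row oracle dataset: Y = X + e with e orthogonal to G, so the Wald
# ratio cov(G,Y)/cov(G,X) = 1 while OLS of Y on X gives 14/11
oracle_data <- data.frame(G = c(0, 0, 1, 1, 2, 2),
                          X = c(0, 1, 1, 2, 2, 3),
                          Y = c(0, 2, 1, 3, 2, 4))

test_that("TSLS equals the Wald ratio and differs from OLS on the oracle data", {
  sp_iv <- model_spec("Y", "X", instruments = "G", estimator = "tsls")
  ft <- fit_tsls(sp_iv, oracle_data)
  expect_equal(coef_table(ft, TRUE)$estimate, 1, tolerance = 1e-10)
  sp_ols <- model_spec("Y", "X")
  fo <- fit_ols(sp_ols, oracle_data)
  expect_equal(coef_table(fo, TRUE)$estimate, 14 / 11, tolerance = 1e-10)
  wald <- cov(oracle_data$G, oracle_data$Y) / cov(oracle_data$G, oracle_data$X)
  expect_equal(coef_table(ft, TRUE)$estimate, wald, tolerance = 1e-10)
})

test_that("just-identified no-covariate TSLS equals the Wald ratio on random data", {
  set.seed(140)
  for (i in 1:5) {
    n <- 200
    d <- data.frame(G = rbinom(n, 2, 0.4))
    d$X <- 0.4 * d$G + rnorm(n)
    d$Y <- -0.7 * d$X + rnorm(n)
    ft <- fit_tsls(model_spec("Y", "X", "G", estimator = "tsls"), d)
    wald <- cov(d$G, d$Y) / cov(d$G, d$X)
    expect_equal(coef_table(ft, TRUE)$estimate, wald, tolerance = 1e-10)
  }
})

test_that("TSLS collapses to OLS when the instrument is the exposure", {
  set.seed(141)
  d <- data.frame(X = rnorm(100))
  d$Y <- 2 * d$X + rnorm(100)
  d$G <- d$X
  ft <- fit_tsls(model_spec("Y", "X", "G", estimator = "tsls"), d)
  fo <- fit_ols(model_spec("Y", "X"), d)
  expect_equal(coef_table(ft)$estimate, coef_table(fo)$estimate,
               tolerance = 1e-10)
  expect_equal(coef_table(ft)$se, coef_table(fo)$se, tolerance = 1e-10)
})

test_that("an exact linear outcome is recovered with zero standard error", {
  d <- data.frame(X = 1:20)
  d$Y <- 3 * d$X - 5
  fo <- fit_ols(model_spec("Y", "X"), d)
  co <- coef_table(fo, TRUE)
  expect_equal(co$estimate, 3, tolerance = 1e-12)
  expect_lt(co$se, 1e-10)
})

test_that("estimates are invariant to row permutation and instrument rescaling,
           equivariant under exposure/outcome rescaling", {
  set.seed(142)
  n <- 300
  d <- data.frame(G = rbinom(n, 2, 0.3), age = runif(n, 40, 70))
  d$X <- 0.3 * d$G + 0.01 * d$age + rnorm(n)
  d$Y <- -0.5 * d$X + 0.02 * d$age + rnorm(n)
  sp <- model_spec("Y", "X", "G", covariates = "age", estimator = "tsls")
  base <- coef_table(fit_tsls(sp, d), TRUE)

  perm <- d[sample(n), ]
  expect_equal(coef_table(fit_tsls(sp, perm), TRUE)$estimate,
               base$estimate, tolerance = 1e-10)

  d2 <- d; d2$G <- 5 * d2$G - 3
  expect_equal(coef_table(fit_tsls(sp, d2), TRUE)$estimate,
               base$estimate, tolerance = 1e-10)

  d3 <- d; d3$X <- d3$X / 2          # doubling the slope
  expect_equal(coef_table(fit_tsls(sp, d3), TRUE)$estimate,
               2 * base$estimate, tolerance = 1e-10)
  d4 <- d; d4$Y <- 3 * d4$Y
  expect_equal(coef_table(fit_tsls(sp, d4), TRUE)$estimate,
               3 * base$estimate, tolerance = 1e-10)
})

test_that("confidence limits reproduce estimate +/- 1.96 SE and p matches |t|", {
  set.seed(143)
  d <- data.frame(G = rbinom(150, 2, 0.4))
  d$X <- 0.4 * d$G + rnorm(150)
  d$Y <- 0.5 * d$X + rnorm(150)
  co <- coef_table(fit_tsls(model_spec("Y", "X", "G", estimator = "tsls"), d))
  expect_equal(co$ci_low, co$estimate - qnorm(0.975) * co$se, tolerance = 1e-12)
  expect_equal(co$ci_high, co$estimate + qnorm(0.975) * co$se, tolerance = 1e-12)
  expect_equal(co$p, 2 * pt(-abs(co$estimate / co$se), df = 150 - 2),
               tolerance = 1e-12)
})

test_that("first-stage F equals the squared t statistic for one instrument", {
  set.seed(144)
  n <- 400
  d <- data.frame(G = rbinom(n, 2, 0.3), age = runif(n, 40, 70),
                  sex = rbinom(n, 1, 0.5))
  d$X <- 0.2 * d$G + 0.01 * d$age + rnorm(n)
  d$Y <- d$X + rnorm(n)
  sp <- model_spec("Y", "X", "G", covariates = c("age", "sex"),
                   estimator = "tsls")
  f <- first_stage_f(sp, d)
  t_fs <- summary(lm(X ~ G + age + sex, d))$coefficients["G", "t value"]
  expect_equal(unname(f), t_fs^2, tolerance = 1e-10)

  # instrument independent of the exposure: central F, mean ~ 1
  set.seed(145)
  fs <- replicate(300, {
    dd <- data.frame(G = rbinom(500, 2, 0.3), X = rnorm(500), Y = rnorm(500))
    first_stage_f(model_spec("Y", "X", "G", estimator = "tsls"), dd)
  })
  expect_lt(abs(mean(fs) - 1), 3 * sd(fs) / sqrt(300))
})

test_that("S-W conditional F reduces exactly to the first-stage F for one exposure", {
  set.seed(146)
  n <- 300
  d <- data.frame(G = rbinom(n, 2, 0.3), age = runif(n, 40, 70))
  d$X <- 0.3 * d$G + rnorm(n)
  d$Y <- d$X + rnorm(n)
  sp <- model_spec("Y", "X", "G", covariates = "age", estimator = "tsls")
  expect_equal(unname(sw_conditional_f(sp, d)),
               unname(first_stage_f(sp, d)), tolerance = 1e-12)
})

test_that("S-W conditional F vanishes when another exposure absorbs the signal", {
  set.seed(147)
  n <- 2000
  d <- data.frame(G1 = rnorm(n), G2 = rnorm(n))
  d$X1 <- 0.5 * d$G1 + rnorm(n, 0, 0.01)
  d$X2 <- d$X1 + rnorm(n, 0, 1e-6)   # second exposure ~ duplicates the first
  d$Y <- d$X1 + rnorm(n)
  sp <- model_spec("Y", c("X1", "X2"), c("G1", "G2"), estimator = "mvmr")
  cf <- sw_conditional_f(sp, d)
  fs <- first_stage_f(sp, d, per_exposure = FALSE)
  expect_lt(cf[["X1"]] / fs[["X1"]], 0.01)
})

test_that("S-W conditional F approximates the standard F for independent exposures", {
  set.seed(148)
  n <- 50000
  d <- data.frame(G1 = rbinom(n, 2, 0.3), G2 = rbinom(n, 2, 0.4))
  d$X1 <- 0.10 * d$G1 + rnorm(n)
  d$X2 <- 0.12 * d$G2 + rnorm(n)
  d$Y <- 0.2 * d$X1 + rnorm(n)
  sp <- model_spec("Y", c("X1", "X2"), c("G1", "G2"), estimator = "mvmr")
  cf <- sw_conditional_f(sp, d)
  fs <- first_stage_f(sp, d)
  expect_lt(abs(cf[["X1"]] - fs[["X1"]]) / fs[["X1"]], 0.1)
  expect_lt(abs(cf[["X2"]] - fs[["X2"]]) / fs[["X2"]], 0.1)
})

test_that("OLS and TSLS agree without confounding and diverge with it", {
  cfg0 <- clean_config(20000, seed = 149, n_variants_per_trait = c(20, 4, 4),
                       target_r2 = c(0.05, 0.0063, 0.0003),
                       confounder_exposures = c(0, 0, 0), confounder_outcome = 0)
  sim <- simulate_cohort(cfg0)
  co <- add_grs(derive_phenotypes(sim$cohort), sim, "neuroticism")
  ft <- coef_table(fit_tsls(model_spec("job_satisfaction", "z_neuroticism",
                                       "grs_neuroticism", analysis_covariates,
                                       "tsls"), co), TRUE)
  fo <- coef_table(fit_ols(model_spec("job_satisfaction", "z_neuroticism",
                                      covariates = analysis_covariates), co),
                   TRUE)
  expect_lt(abs(ft$estimate - fo$estimate), 3 * ft$se)

  # omitted-variable bias pushes OLS in the direction of the loading product
  cfg1 <- clean_config(20000, seed = 150, n_variants_per_trait = c(20, 4, 4),
                       target_r2 = c(0.05, 0.0063, 0.0003),
                       true_effects = c(-0.31, 0, 0),
                       exposure_correlation = diag(3),
                       confounder_exposures = c(0.4, 0, 0),
                       confounder_outcome = 0.4)
  sim1 <- simulate_cohort(cfg1)
  co1 <- add_grs(derive_phenotypes(sim1$cohort), sim1, "neuroticism")
  fo1 <- coef_table(fit_ols(model_spec("job_satisfaction", "z_neuroticism",
                                       covariates = analysis_covariates), co1),
                    TRUE)
  expect_gt(fo1$estimate - (-0.31), 4 * fo1$se)  # biased upward (+0.16 expected)
})

test_that("MVMR matches univariable TSLS for independent exposures and instruments", {
  cfg <- clean_config(20000, seed = 151, n_variants_per_trait = c(20, 20, 20),
                      target_r2 = c(0.05, 0.05, 0.05),
                      true_effects = c(-0.3, 0.1, 0),
                      exposure_correlation = diag(3),
                      confounder_exposures = c(0, 0, 0), confounder_outcome = 0)
  sim <- simulate_cohort(cfg)
  co <- add_grs(derive_phenotypes(sim$cohort), sim)
  spm <- model_spec("job_satisfaction", unname(trait_z_cols),
                    paste0("grs_", names(trait_z_cols)),
                    analysis_covariates, "mvmr")
  fm <- coef_table(fit_mvmr(spm, co), TRUE)
  for (t in names(trait_z_cols)) {
    sp1 <- model_spec("job_satisfaction", trait_z_cols[[t]],
                      paste0("grs_", t), analysis_covariates, "tsls")
    f1 <- coef_table(fit_tsls(sp1, co), TRUE)
    row <- fm[fm$term == trait_z_cols[[t]], ]
    expect_lt(abs(row$estimate - f1$estimate),
              3 * sqrt(row$se^2 + f1$se^2))
  }
})

test_that("degenerate designs raise informative errors", {
  d <- data.frame(Y = rnorm(10), X = rnorm(10), G = rep(1, 10))
  expect_error(fit_tsls(model_spec("Y", "X", "G", estimator = "tsls"), d),
               "rank|partial variance")
  expect_error(model_spec("Y", c("X1", "X2"), "G", estimator = "mvmr"),
               "at least as many instruments")
  expect_error(fit_ols(model_spec("Y", "X"), d[0, ]), "observations")
  d2 <- data.frame(Y = rnorm(10), X = rnorm(10))
  d2$X2 <- d2$X
  expect_error(fit_ols(model_spec("Y", c("X", "X2")), d2), "rank")
})
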