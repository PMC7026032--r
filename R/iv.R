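#' Model specification for observational and instrumental-variable fits
#'
#' @param outcome outcome column name.
#' @param exposures one to three exposure column names.
#' @param instruments instrument column names (GRS columns); required for
#'   `tsls` (>= 1) and `mvmr` (at least as many as exposures).
#' @param covariates covariate column names; factors (e.g. assessment
#'   centre) are reference-coded with the first sorted level as reference.
#' @param estimator `"ols"`, `"tsls"` or `"mvmr"`.
#' @param instrumenting `"own"` instruments each exposure with its own
#'   score (the multi-stage procedure); `"all"` is textbook two-stage least
#'   squares with the full instrument set.
#' @param dof residual-variance divisor: `"n-k"` (default) or `"n"`.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(outcome, exposures, instruments = character(),
                       covariates = character(),
                       estimator = c("ols", "tsls", "mvmr"),
                       instrumenting = c("own", "all"),
                       dof = c("n-k", "n")) {
  estimator <- match.arg(estimator)
  instrumenting <- match.arg(instrumenting)
  dof <- match.arg(dof)
  if (length(exposures) < 1L || length(exposures) > 3L)
    stop("between one and three exposures required")
  if (estimator == "tsls" && length(instruments) < 1L)
    stop("tsls requires at least one instrument")
  if (estimator == "mvmr" && length(instruments) < length(exposures))
    stop("mvmr requires at least as many instruments as exposures")
  structure(list(outcome = outcome, exposures = exposures,
                 instruments = instruments, covariates = covariates,
                 estimator = estimator, instrumenting = instrumenting,
                 dof = dof),
            class = "model_spec")
}

# expand covariates to a numeric design block (no intercept), dummy-coding
# factors against their first level
covariate_block <- function(data, covariates) {
  if (!length(covariates)) {
    return(matrix(numeric(0), nrow(data), 0))
  }
  mm <- model.matrix(~ ., data = data[, covariates, drop = FALSE])
  mm[, -1, drop = FALSE]
}

analysis_frame <- function(spec, data) {
  vars <- unique(c(spec$outcome, spec$exposures, spec$instruments,
                   spec$covariates))
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols))
    stop("column(s) not found: ", paste(missing_cols, collapse = ", "))
  use <- complete.cases(data[, vars, drop = FALSE])
  d <- data[use, vars, drop = FALSE]
  if (!nrow(d)) stop("no complete observations")
  d[] <- lapply(d, function(x) if (is.factor(x)) droplevels(x) else x)
  d
}

new_iv_fit <- function(estimator, terms, estimate, se, n, k, dof_used,
                       diagnostics = list(), spec = NULL) {
  tval <- estimate / se
  p <- 2 * pt(-abs(tval), df = n - k)
  z <- qnorm(0.975)
  structure(list(
    estimator = estimator,
    coefficients = data.frame(term = terms,
                              estimate = estimate,
                              se = se,
                              ci_low = estimate - z * se,
                              ci_high = estimate + z * se,
                              p = p,
                              stringsAsFactors = FALSE,
                              row.names = NULL),
    n = n, k = k, dof_used = dof_used,
    diagnostics = diagnostics,
    spec = spec
  ), class = "iv_fit")
}

#' @export
print.iv_fit <- function(x, digits = 4, ...) {
  cat(sprintf("%s fit: n = %d\n", toupper(x$estimator), x$n))
  co <- x$coefficients
  show <- if (!is.null(x$spec)) co$term %in% c(x$spec$exposures, "(Intercept)") else TRUE
  co <- co[show, , drop = FALSE]
  co[-1] <- lapply(co[-1], signif, digits)
  print(co, row.names = FALSE)
  fs <- x$diagnostics$first_stage_f
  if (!is.null(fs))
    cat("first-stage F:",
        paste(sprintf("%s = %.1f%s", names(fs), fs,
                      ifelse(fs < 10, " [WEAK]", "")), collapse = ", "), "\n")
  cf <- x$diagnostics$conditional_f
  if (!is.null(cf))
    cat("conditional (S-W) F:",
        paste(sprintf("%s = %.1f%s", names(cf), cf,
                      ifelse(cf < 10, " [WEAK]", "")), collapse = ", "), "\n")
  invisible(x)
}

#' Tidy coefficient table of a fit
#'
#' @param fit an `iv_fit`.
#' @param exposures_only keep only the exposure rows.
#' @return data.frame of terms with estimates, standard errors, normal 95%
#'   confidence limits and two-sided p-values.
#' @export
coef_table <- function(fit, exposures_only = FALSE) {
  co <- fit$coefficients
  if (exposures_only && !is.null(fit$spec))
    co <- co[co$term %in% fit$spec$exposures, , drop = FALSE]
  co
}

#' Ordinary least squares with classical standard errors
#'
#' Univariable (one exposure) or multivariable (all exposures together)
#' observational regression of the outcome on exposure z-scores and
#' covariates.
#'
#' @param spec a [model_spec()].
#' @param data cohort data.frame.
#' @return an `iv_fit`.
#' @export
fit_ols <- function(spec, data) {
  d <- analysis_frame(spec, data)
  y <- d[[spec$outcome]]
  X <- cbind("(Intercept)" = 1,
             as.matrix(d[, spec$exposures, drop = FALSE]),
             covariate_block(d, spec$covariates))
  n <- nrow(X); k <- ncol(X)
  if (n <= k) stop("more parameters than observations")
  qx <- qr(X)
  if (qx$rank < k) stop("rank-deficient design")
  beta <- qr.coef(qx, y)
  res <- y - drop(X %*% beta)
  dof_used <- if (spec$dof == "n-k") n - k else n
  sigma2 <- sum(res^2) / dof_used
  V <- sigma2 * chol2inv(qr.R(qx))
  new_iv_fit("ols", colnames(X), unname(beta), sqrt(diag(V)),
             n, k, dof_used, spec = spec)
}

# shared 2SLS engine: exposures Xe instrumented by G, covariates C in both
# stages; SEs use residuals computed with the observed exposures
tsls_engine <- function(y, Xe, G, C, dof = "n-k") {
  n <- length(y)
  Z <- cbind("(Intercept)" = 1, C, G)
  qz <- qr(Z)
  if (qz$rank < ncol(Z)) stop("instrument/covariate matrix is rank deficient")
  Xhat_e <- qr.fitted(qz, Xe)
  X <- cbind("(Intercept)" = 1, Xe, C)
  Xhat <- cbind("(Intercept)" = 1, Xhat_e, C)
  k <- ncol(X)
  qxh <- qr(Xhat)
  if (qxh$rank < k)
    stop("instrument has no partial variance after covariate projection")
  beta <- qr.coef(qxh, y)
  res <- y - drop(X %*% beta)   # observed-exposure residuals (IV correction)
  dof_used <- if (dof == "n-k") n - k else n
  sigma2 <- sum(res^2) / dof_used
  V <- sigma2 * chol2inv(qr.R(qxh))
  list(beta = beta, se = sqrt(diag(V)), n = n, k = k, dof_used = dof_used,
       first_stage_fitted = Xhat_e)
}

# partial F of the instrument block: x ~ C + G vs x ~ C
partial_f <- function(x, G, C) {
  n <- length(x)
  Z0 <- cbind(1, C)
  Z1 <- cbind(Z0, G)
  q0 <- qr(Z0); q1 <- qr(Z1)
  rss0 <- sum(qr.resid(q0, x)^2)
  rss1 <- sum(qr.resid(q1, x)^2)
  df_num <- q1$rank - q0$rank
  df_den <- n - q1$rank
  f <- ((rss0 - rss1) / df_num) / (rss1 / df_den)
  list(f = f, df_num = df_num, df_den = df_den,
       p = pf(f, df_num, df_den, lower.tail = FALSE),
       r2_partial = (rss0 - rss1) / rss0)
}

#' Two-stage least squares (univariable Mendelian randomisation)
#'
#' First stage regresses the exposure on its instrument(s) and covariates;
#' second stage regresses the outcome on the genetically predicted exposure
#' with the same covariates. Standard errors use the standard IV
#' correction: residuals are computed with the observed (not fitted)
#' exposure and the residual variance divisor is n-k by default.
#'
#' @param spec a [model_spec()] with one exposure.
#' @param data cohort data.frame.
#' @return an `iv_fit` with first-stage F and R-squared diagnostics.
#' @export
fit_tsls <- function(spec, data) {
  if (length(spec$exposures) != 1L)
    stop("fit_tsls takes exactly one exposure; use fit_mvmr for several")
  if (length(spec$instruments) < 1L) stop("no instrument specified")
  d <- analysis_frame(spec, data)
  y <- d[[spec$outcome]]
  Xe <- as.matrix(d[, spec$exposures, drop = FALSE])
  G <- as.matrix(d[, spec$instruments, drop = FALSE])
  C <- covariate_block(d, spec$covariates)
  eng <- tsls_engine(y, Xe, G, C, spec$dof)
  fs <- partial_f(Xe[, 1], G, C)
  diag_list <- list(first_stage_f = setNames(fs$f, spec$exposures),
                    first_stage_df = c(fs$df_num, fs$df_den),
                    first_stage_r2 = setNames(fs$r2_partial, spec$exposures))
  new_iv_fit("tsls", names(eng$beta), unname(eng$beta), eng$se,
             eng$n, eng$k, eng$dof_used, diag_list, spec)
}

#' Multivariable Mendelian randomisation
#'
#' Estimates the direct effect of each exposure conditional on the others.
#' In the default `"own"` instrumenting mode each exposure's fitted values
#' come from its own instrument (the multi-stage procedure: one first-stage
#' regression per trait, then one second-stage regression on all fitted
#' values together); `"all"` mode is textbook 2SLS using the full
#' instrument set in every first stage. Covariates enter every stage;
#' standard errors use observed-exposure residuals as in [fit_tsls()].
#'
#' Reports the per-exposure first-stage F (own instrument) and the
#' Sanderson-Windmeijer conditional F.
#'
#' @param spec a [model_spec()] whose `instruments` are matched to
#'   `exposures` by position in `"own"` mode.
#' @param data cohort data.frame.
#' @return an `iv_fit`.
#' @export
fit_mvmr <- function(spec, data) {
  p <- length(spec$exposures)
  if (length(spec$instruments) < p)
    stop("mvmr needs at least as many instruments as exposures")
  d <- analysis_frame(spec, data)
  y <- d[[spec$outcome]]
  Xe <- as.matrix(d[, spec$exposures, drop = FALSE])
  G <- as.matrix(d[, spec$instruments, drop = FALSE])
  C <- covariate_block(d, spec$covariates)
  n <- nrow(Xe)

  if (spec$instrumenting == "all") {
    eng <- tsls_engine(y, Xe, G, C, spec$dof)
    beta <- eng$beta; se <- eng$se; k <- eng$k; dof_used <- eng$dof_used
  } else {
    if (length(spec$instruments) != p)
      stop("own-instrument mode pairs each exposure with one instrument column")
    Xhat <- Xe
    for (j in seq_len(p)) {
      qj <- qr(cbind(1, C, G[, j]))
      Xhat[, j] <- qr.fitted(qj, Xe[, j])
    }
    W <- cbind("(Intercept)" = 1, Xhat, C)
    k <- ncol(W)
    qw <- qr(W)
    if (qw$rank < k) stop("fitted values are collinear")
    beta <- qr.coef(qw, y)
    X <- cbind("(Intercept)" = 1, Xe, C)
    res <- y - drop(X %*% beta)
    dof_used <- if (spec$dof == "n-k") n - k else n
    sigma2 <- sum(res^2) / dof_used
    V <- sigma2 * chol2inv(qr.R(qw))
    se <- sqrt(diag(V))
  }

  fs <- vapply(seq_len(p), function(j) {
    Gj <- if (spec$instrumenting == "own") G[, j, drop = FALSE] else G
    partial_f(Xe[, j], Gj, C)$f
  }, numeric(1))
  cf <- sw_conditional_f(spec, data)
  diag_list <- list(first_stage_f = setNames(fs, spec$exposures),
                    conditional_f = cf)
  new_iv_fit("mvmr", names(beta), unname(beta), se, n, k, dof_used,
             diag_list, spec)
}

#' First-stage (instrument-strength) F statistic
#'
#' Partial F for the instrument block in the first-stage regression
#' `exposure ~ instruments + covariates` versus `exposure ~ covariates`.
#' With a single instrument this equals the squared first-stage
#' t-statistic.
#'
#' @param spec a [model_spec()].
#' @param data cohort data.frame.
#' @param per_exposure in `"own"` mode, use each exposure's own instrument;
#'   otherwise the full instrument set.
#' @return named vector of F statistics, one per exposure.
#' @export
first_stage_f <- function(spec, data, per_exposure = spec$instrumenting == "own") {
  d <- analysis_frame(spec, data)
  Xe <- as.matrix(d[, spec$exposures, drop = FALSE])
  G <- as.matrix(d[, spec$instruments, drop = FALSE])
  C <- covariate_block(d, spec$covariates)
  out <- vapply(seq_along(spec$exposures), function(j) {
    Gj <- if (per_exposure && ncol(G) >= j) G[, j, drop = FALSE] else G
    partial_f(Xe[, j], Gj, C)$f
  }, numeric(1))
  setNames(out, spec$exposures)
}

#' Sanderson-Windmeijer conditional F statistic
#'
#' Instrument strength for each exposure conditional on the other
#' exposures: the exposure's dependence on the others is first estimated by
#' instrumental variables with the full instrument set, the residualised
#' exposure is then regressed on all instruments and covariates, and the
#' instruments' joint F is reported with numerator degrees of freedom
#' (number of instruments - number of exposures + 1). With one exposure it
#' reduces exactly to the standard first-stage F.
#'
#' @param spec a [model_spec()] with at least as many instruments as
#'   exposures.
#' @param data cohort data.frame.
#' @return named vector of conditional F statistics.
#' @export
sw_conditional_f <- function(spec, data) {
  p <- length(spec$exposures)
  kz <- length(spec$instruments)
  if (kz < p) stop("not identified: fewer instruments than exposures")
  d <- analysis_frame(spec, data)
  Xe <- as.matrix(d[, spec$exposures, drop = FALSE])
  G <- as.matrix(d[, spec$instruments, drop = FALSE])
  C <- covariate_block(d, spec$covariates)
  n <- nrow(Xe)
  df_num <- kz - p + 1L

  out <- vapply(seq_len(p), function(j) {
    xj <- Xe[, j]
    if (p > 1L) {
      others <- Xe[, -j, drop = FALSE]
      eng <- tsls_engine(xj, others, G, C)
      delta <- eng$beta[colnames(others)]
      xj <- xj - drop(others %*% delta)
    }
    Z0 <- cbind(1, C)
    Z1 <- cbind(Z0, G)
    q0 <- qr(Z0); q1 <- qr(Z1)
    rss0 <- sum(qr.resid(q0, xj)^2)
    rss1 <- sum(qr.resid(q1, xj)^2)
    ((rss0 - rss1) / df_num) / (rss1 / (n - q1$rank))
  }, numeric(1))
  setNames(out, spec$exposures)
}
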