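#' Non-centrality parameter for MR with a continuous outcome
#'
#' `NCP = n * r2_gx * beta_std^2`, where `r2_gx` is the fraction of
#' exposure variance explained by the instrument and `beta_std` the
#' hypothesised causal effect in standardised units (outcome SDs per
#' exposure SD).
#'
#' @param n sample size (>= 2).
#' @param r2_gx instrument R-squared, in (0, 1).
#' @param beta_std standardised causal effect.
#' @return the non-centrality parameter.
#' @examples
#' mr_ncp(73296, 0.0114, 0.30)
#' @export
mr_ncp <- function(n, r2_gx, beta_std) {
  check_power_query(n, r2_gx, beta_std, alpha = 0.05)
  n * r2_gx * beta_std^2
}

#' Analytic power of the MR test
#'
#' Normal approximation used by standard MR power tools:
#' `power = 1 - Phi(z_{1-alpha/2} - sqrt(NCP)) + Phi(-z_{1-alpha/2} - sqrt(NCP))`
#' for a two-sided test at level `alpha`. At `beta_std = 0` the power
#' equals `alpha` exactly.
#'
#' @inheritParams mr_ncp
#' @param alpha two-sided significance level, in (0, 1).
#' @return power in \[0, 1\].
#' @examples
#' mr_power(73296, 0.0114, 0.30)      # essentially 1
#' mr_power(1000, 0.01, 0.2)          # ~0.097
#' @export
mr_power <- function(n, r2_gx, beta_std, alpha = 0.05) {
  check_power_query(n, r2_gx, beta_std, alpha)
  z <- qnorm(1 - alpha / 2)
  s <- sqrt(n * r2_gx * beta_std^2)
  pnorm(z - s, lower.tail = FALSE) + pnorm(-z - s)
}

#' Power for a raw-scale effect
#'
#' Convenience wrapper converting a raw-scale causal effect to standardised
#' units via `beta_std = beta_raw * sd_x / sd_y`.
#'
#' @inheritParams mr_power
#' @param beta_raw causal effect on the raw outcome scale per raw unit of
#'   exposure.
#' @param sd_x,sd_y exposure and outcome standard deviations.
#' @return power in \[0, 1\].
#' @export
mr_power_raw <- function(n, r2_gx, beta_raw, sd_x, sd_y, alpha = 0.05) {
  mr_power(n, r2_gx, beta_raw * sd_x / sd_y, alpha)
}

#' Smallest sample size reaching a target power
#'
#' Monotone bisection over integer n.
#'
#' @param power_target desired power, in (alpha, 1).
#' @inheritParams mr_power
#' @return the smallest integer n with `mr_power(n, ...) >= power_target`.
#' @export
mr_min_n <- function(power_target, r2_gx, beta_std, alpha = 0.05) {
  if (beta_std == 0) stop("unreachable target: zero effect size")
  if (power_target <= alpha || power_target >= 1)
    stop("power_target must lie in (alpha, 1)")
  lo <- 2L
  hi <- 2L
  while (mr_power(hi, r2_gx, beta_std, alpha) < power_target) {
    if (hi > 2^40) stop("unreachable target")
    hi <- hi * 2L
  }
  while (hi - lo > 1L) {
    mid <- lo + (hi - lo) %/% 2L
    if (mr_power(mid, r2_gx, beta_std, alpha) >= power_target) hi <- mid else lo <- mid
  }
  if (mr_power(lo, r2_gx, beta_std, alpha) >= power_target) lo else hi
}

check_power_query <- function(n, r2_gx, beta_std, alpha) {
  if (any(n < 2)) stop("n must be at least 2")
  if (any(r2_gx <= 0 | r2_gx >= 1)) stop("r2_gx must lie in (0, 1)")
  if (any(alpha <= 0 | alpha >= 1)) stop("alpha must lie in (0, 1)")
  if (any(!is.finite(beta_std))) stop("beta_std must be finite")
  invisible(TRUE)
}
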