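`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a deterministic per-component seed from the run seed
#'
#' One global integer seed drives the whole simulation; each stochastic
#' component (genotypes, covariates, exposures, outcome, ...) draws from its
#' own sub-stream so that adding draws to one component never perturbs the
#' others.
#'
#' @param seed integer run seed.
#' @param component character tag of the component.
#' @return an integer seed below 2^31.
#' @keywords internal
component_seed <- function(seed, component) {
  codes <- utf8ToInt(component)
  offset <- sum(codes * seq_along(codes))
  as.integer((abs(as.numeric(seed)) * 1009 + offset * 97) %% 2147483587)
}

# Evaluate `expr` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

stop_stage <- function(stage, e) {
  stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)), call. = FALSE)
}
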