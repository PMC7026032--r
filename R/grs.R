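#' Per-variant genotype quality control
#'
#' Removes variants whose call rate falls strictly below `min_call_rate`
#' (the default keeps variants at exactly 90%). Removals are recorded with
#' their call rates.
#'
#' @param genotypes a [genotype_matrix()].
#' @param min_call_rate minimum fraction of non-missing calls, in (0, 1\].
#' @return the filtered [genotype_matrix()] with a `"removed_variants"`
#'   attribute.
#' @export
variant_qc <- function(genotypes, min_call_rate = 0.90) {
  if (min_call_rate <= 0 || min_call_rate > 1)
    stop("min_call_rate must lie in (0, 1]")
  cr <- call_rates(genotypes)
  drop <- cr < min_call_rate
  if (all(drop)) stop("all variants fail the call-rate filter")
  removed <- data.frame(variant_id = genotypes$variants$variant_id[drop],
                        call_rate = unname(cr[drop]),
                        reason = rep("call_rate_below_threshold", sum(drop)),
                        stringsAsFactors = FALSE)
  out <- subset_variants(genotypes, genotypes$variants$variant_id[!drop])
  attr(out, "removed_variants") <- removed
  out
}

#' Align genotype dosages to the instrument risk alleles
#'
#' Re-expresses every dosage as the count of the instrument's effect (risk)
#' allele: when the genotype file is oriented on the other allele the
#' dosage becomes `2 - dosage` and the allele metadata are swapped.
#' Variants whose allele pair does not match the instrument record are
#' dropped with a warning (no strand-flip guessing), as are
#' strand-ambiguous A/T and C/G variants under `strict = TRUE`.
#'
#' @param genotypes a [genotype_matrix()].
#' @param instruments instrument table (see [read_instruments()]).
#' @param strict drop strand-ambiguous variants.
#' @return an aligned [genotype_matrix()] restricted to instrument
#'   variants.
#' @export
align_effect_alleles <- function(genotypes, instruments, strict = TRUE) {
  idx <- match(instruments$variant_id, genotypes$variants$variant_id)
  if (anyNA(idx)) {
    warning("instrument variant(s) absent from genotypes skipped: ",
            paste(instruments$variant_id[is.na(idx)], collapse = ", "))
    instruments <- instruments[!is.na(idx), , drop = FALSE]
    idx <- idx[!is.na(idx)]
  }
  g <- subset_variants(genotypes, instruments$variant_id)
  v <- g$variants
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  keep <- rep(TRUE, nrow(v))
  for (j in seq_len(nrow(v))) {
    ea <- instruments$effect_allele[j]
    oa <- instruments$other_allele[j]
    if (strict && comp[[ea]] == oa) {
      warning("strand-ambiguous variant dropped: ", v$variant_id[j])
      keep[j] <- FALSE
      next
    }
    if (v$effect_allele[j] == ea && v$other_allele[j] == oa) {
      # already counts the risk allele
    } else if (v$effect_allele[j] == oa && v$other_allele[j] == ea) {
      g$dosages[, j] <- 2 - g$dosages[, j]
      v$effect_allele[j] <- ea
      v$other_allele[j] <- oa
      v$eaf[j] <- 1 - v$eaf[j]
    } else {
      warning("allele pair mismatch for ", v$variant_id[j],
              "; variant dropped")
      keep[j] <- FALSE
    }
  }
  v$trait <- instruments$trait
  g$variants <- v
  out <- genotype_matrix(g$dosages[, keep, drop = FALSE],
                         v[keep, , drop = FALSE], g$sample_ids)
  comp <- attr(g, "complete_dosages")
  if (!is.null(comp)) attr(out, "complete_dosages") <- comp[, keep, drop = FALSE]
  out
}

#' Unweighted genetic risk score
#'
#' Sums the effect-allele dosages over a trait's instrument panel. Missing
#' dosages are either mean-imputed as twice the in-sample effect-allele
#' frequency (default) or skipped for that sample (`missing = "drop"`).
#' With no missingness the score is the integer count of risk alleles.
#'
#' @param genotypes an aligned, QC'd [genotype_matrix()].
#' @param instruments instrument table.
#' @param trait trait label selecting the panel.
#' @param missing `"impute"` or `"drop"` (drop-variant-for-sample).
#' @return an object of class `grs_result` with fields `score`,
#'   `n_variants_used`, `call_rate`, `trait`.
#' @export
compute_unweighted_grs <- function(genotypes, instruments, trait,
                                   missing = c("impute", "drop")) {
  missing <- match.arg(missing)
  panel <- instruments$variant_id[instruments$trait == trait]
  panel <- intersect(panel, genotypes$variants$variant_id)
  if (!length(panel)) stop("empty instrument panel for trait '", trait, "'")
  g <- subset_variants(genotypes, panel)
  d <- g$dosages
  if (anyNA(d)) {
    if (missing == "impute") {
      eaf_hat <- colMeans(d, na.rm = TRUE) / 2
      idx <- which(is.na(d), arr.ind = TRUE)
      d[idx] <- 2 * eaf_hat[idx[, 2]]
      score <- rowSums(d)
    } else {
      score <- rowSums(d, na.rm = TRUE)
    }
  } else {
    score <- rowSums(d)
  }
  structure(list(score = setNames(score, g$sample_ids),
                 n_variants_used = length(panel),
                 call_rate = call_rates(g),
                 trait = trait,
                 missing = missing),
            class = "grs_result")
}

#' @export
print.grs_result <- function(x, ...) {
  cat(sprintf("unweighted GRS for %s: %d variants, %d samples\n",
              x$trait, x$n_variants_used, length(x$score)))
  cat(sprintf("  score range: %.1f - %.1f (bound 0 - %d)\n",
              min(x$score), max(x$score), 2L * x$n_variants_used))
  invisible(x)
}

#' Variance in a trait explained by its genetic risk score
#'
#' Incremental R-squared of the GRS over an age + sex baseline:
#' `R2(trait ~ GRS + age + sex) - R2(trait ~ age + sex)`, together with the
#' GRS slope and standard error on the trait scale.
#'
#' @param grs a `grs_result` or a numeric score vector.
#' @param trait_z trait values (typically a z-score).
#' @param age,sex adjustment covariates.
#' @return list with `r2` (fraction), `beta`, `se`, `p`, `n`.
#' @export
variance_explained <- function(grs, trait_z, age, sex) {
  score <- if (inherits(grs, "grs_result")) grs$score else grs
  ok <- complete.cases(score, trait_z, age, sex)
  if (sum(ok) < 3L) stop("need at least 3 complete samples")
  score <- score[ok]; trait_z <- trait_z[ok]; age <- age[ok]; sex <- sex[ok]
  if (var(score) == 0) stop("GRS has zero variance")
  full <- lm(trait_z ~ score + age + sex)
  base <- lm(trait_z ~ age + sex)
  if (any(is.na(coef(full)))) stop("collinear design in variance_explained")
  sm <- summary(full)
  r2 <- sm$r.squared - summary(base)$r.squared
  list(r2 = r2,
       beta = unname(coef(full)["score"]),
       se = unname(sm$coefficients["score", "Std. Error"]),
       p = unname(sm$coefficients["score", "Pr(>|t|)"]),
       n = sum(ok))
}
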