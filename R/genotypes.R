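#' Genotype dosage container
#'
#' A samples-by-variants matrix of effect-allele dosages in {0, 1, 2, NA}
#' plus per-variant allele metadata. Dosages count the effect (risk) allele.
#'
#' @param dosages numeric matrix, samples in rows, variants in columns;
#'   entries must be 0, 1, 2 or NA.
#' @param variants data.frame with columns `variant_id`, `effect_allele`,
#'   `other_allele`, `eaf`, `trait` (one row per dosage column).
#' @param sample_ids character vector of row identifiers.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, variants, sample_ids) {
  dosages <- as.matrix(dosages)
  if (!is.numeric(dosages)) stop("dosages must be numeric")
  vals <- dosages[!is.na(dosages)]
  if (length(vals) && !all(vals %in% c(0, 1, 2)))
    stop("dosages must be 0, 1, 2 or NA")
  need <- c("variant_id", "effect_allele", "other_allele", "eaf", "trait")
  if (!all(need %in% names(variants)))
    stop("variants must have columns: ", paste(need, collapse = ", "))
  if (nrow(variants) != ncol(dosages))
    stop("one variant record per dosage column required")
  if (anyDuplicated(variants$variant_id))
    stop("duplicated variant_id")
  if (length(sample_ids) != nrow(dosages))
    stop("one sample id per dosage row required")
  if (any(variants$eaf < 0 | variants$eaf > 1))
    stop("eaf must lie in [0, 1]")
  dimnames(dosages) <- list(sample_ids, variants$variant_id)
  structure(list(dosages = dosages,
                 variants = as.data.frame(variants, stringsAsFactors = FALSE),
                 sample_ids = as.character(sample_ids)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants\n",
              nrow(x$dosages), ncol(x$dosages)))
  tab <- table(x$variants$trait)
  cat("  panels:", paste(sprintf("%s=%d", names(tab), tab), collapse = "  "), "\n")
  miss <- mean(is.na(x$dosages))
  cat(sprintf("  missing dosages: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' Subset a genotype matrix to a set of variants
#'
#' @param genotypes a `genotype_matrix`.
#' @param variant_ids variant identifiers to keep, in the order given.
#' @return a `genotype_matrix` restricted to the requested variants.
#' @export
subset_variants <- function(genotypes, variant_ids) {
  idx <- match(variant_ids, genotypes$variants$variant_id)
  if (anyNA(idx)) stop("unknown variant ids: ",
                       paste(variant_ids[is.na(idx)], collapse = ", "))
  out <- genotype_matrix(genotypes$dosages[, idx, drop = FALSE],
                         genotypes$variants[idx, , drop = FALSE],
                         genotypes$sample_ids)
  comp <- attr(genotypes, "complete_dosages")
  if (!is.null(comp)) attr(out, "complete_dosages") <- comp[, idx, drop = FALSE]
  out
}

# per-variant fraction of non-missing calls
call_rates <- function(genotypes) {
  colMeans(!is.na(genotypes$dosages))
}
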