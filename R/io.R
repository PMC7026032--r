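#' Write genotypes as a tab-separated dosage matrix plus variant side-car
#'
#' The dosage file has a `sample_id` column followed by one column per
#' variant; missing dosages are encoded `NA`. The side-car carries the
#' variant metadata (`variant_id`, `effect_allele`, `other_allele`, `eaf`,
#' `trait`).
#'
#' @param genotypes a [genotype_matrix()].
#' @param path output path for the dosage matrix.
#' @param variant_path output path for the variant side-car.
#' @return `path`, invisibly.
#' @export
write_genotypes_tsv <- function(genotypes, path, variant_path) {
  d <- as.data.frame(genotypes$dosages)
  out <- cbind(data.frame(sample_id = genotypes$sample_ids,
                          stringsAsFactors = FALSE), d)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(genotypes$variants[, c("variant_id", "effect_allele",
                                     "other_allele", "eaf", "trait")],
              variant_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write genotypes as a minimal VCF 4.2 with GT genotypes
#'
#' REF is the other allele and ALT the effect allele, so the ALT-allele
#' count of the GT field equals the stored effect-allele dosage. Missing
#' dosages become `./.`.
#'
#' @param genotypes a [genotype_matrix()].
#' @param path output `.vcf` path.
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(genotypes, path) {
  v <- genotypes$variants
  gt_codes <- c("0/0", "0/1", "1/1")
  d <- genotypes$dosages
  gt <- matrix("./.", nrow(d), ncol(d))
  ok <- !is.na(d)
  gt[ok] <- gt_codes[d[ok] + 1L]
  body <- cbind("1", as.character(seq_len(nrow(v))), v$variant_id,
                v$other_allele, v$effect_allele, ".", "PASS", ".", "GT",
                t(gt))
  lines <- c("##fileformat=VCFv4.2",
             "##source=grsmr",
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", genotypes$sample_ids), collapse = "\t"),
             apply(body, 1, paste, collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read genotypes from dosage TSV or minimal VCF
#'
#' Both dialects round-trip with the writers. For VCF input the GT fields
#' are converted to effect-allele dosages using the variant side-car to
#' decide which VCF allele is the effect allele; a variant whose allele
#' pair disagrees with the side-car is dropped with a warning.
#'
#' @param path dosage TSV or VCF path.
#' @param format `"tsv"` or `"vcf"`.
#' @param variant_file variant side-car path (required).
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf"), variant_file) {
  format <- match.arg(format)
  variants <- read.delim(variant_file, stringsAsFactors = FALSE)
  need <- c("variant_id", "effect_allele", "other_allele", "trait")
  if (!all(need %in% names(variants)))
    stop("malformed variant side-car: need columns ",
         paste(need, collapse = ", "))
  if (anyDuplicated(variants$variant_id))
    stop("duplicated variant id in side-car")

  if (format == "tsv") {
    tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    if (names(tab)[1] != "sample_id")
      stop("malformed dosage header: first column must be 'sample_id'")
    sample_ids <- tab$sample_id
    d <- as.matrix(tab[, -1, drop = FALSE])
    present <- variants$variant_id %in% colnames(d)
    if (!all(present)) {
      warning("variant(s) absent from genotype file skipped: ",
              paste(variants$variant_id[!present], collapse = ", "))
      variants <- variants[present, , drop = FALSE]
    }
    d <- d[, variants$variant_id, drop = FALSE]
    if (is.null(variants$eaf)) variants$eaf <- colMeans(d, na.rm = TRUE) / 2
    return(genotype_matrix(d, variants, sample_ids))
  }

  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  sample_ids <- colnames(gt)
  alt_count <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  known <- c("0/0" = 0, "0/1" = 1, "1/0" = 1, "1/1" = 2,
             "0|0" = 0, "0|1" = 1, "1|0" = 1, "1|1" = 2)
  alt_count[] <- known[gt]

  idx <- match(variants$variant_id, fix$ID)
  if (anyNA(idx)) {
    warning("variant(s) absent from VCF skipped: ",
            paste(variants$variant_id[is.na(idx)], collapse = ", "))
    variants <- variants[!is.na(idx), , drop = FALSE]
    idx <- idx[!is.na(idx)]
  }
  d <- matrix(NA_real_, length(sample_ids), length(idx),
              dimnames = list(sample_ids, variants$variant_id))
  keep <- rep(TRUE, length(idx))
  for (j in seq_along(idx)) {
    ref <- fix$REF[idx[j]]
    alt <- fix$ALT[idx[j]]
    if (variants$effect_allele[j] == alt && variants$other_allele[j] == ref) {
      d[, j] <- alt_count[idx[j], ]
    } else if (variants$effect_allele[j] == ref &&
               variants$other_allele[j] == alt) {
      d[, j] <- 2 - alt_count[idx[j], ]
    } else {
      warning("allele mismatch between VCF and side-car for ",
              variants$variant_id[j], "; variant dropped")
      keep[j] <- FALSE
    }
  }
  variants <- variants[keep, , drop = FALSE]
  d <- d[, keep, drop = FALSE]
  if (is.null(variants$eaf)) variants$eaf <- colMeans(d, na.rm = TRUE) / 2
  genotype_matrix(d, variants, sample_ids)
}

#' Write / read a cohort table
#'
#' Tab-separated with a fixed, documented column order (identifier,
#' covariates, employment, raw exposures, outcome, flags, then any derived
#' or latent columns); missing values are encoded `NA`.
#'
#' @param cohort cohort data.frame.
#' @param path file path.
#' @return `path` (writer) or the cohort data.frame (reader).
#' @export
write_cohort_tsv <- function(cohort, path) {
  lead <- intersect(c("sample_id", "age", "sex", "centre", "tdi", "bmi",
                      "employed", "neuroticism_score", "qualification",
                      "walk_days", "walk_min", "mod_days", "mod_min",
                      "vig_days", "vig_min", "job_satisfaction",
                      "consent_withdrawn", "sex_mismatch", "related",
                      "non_british", "icd10_mental_neuro",
                      "neuroticism_missing"),
                    names(cohort))
  cohort <- cohort[, c(lead, setdiff(names(cohort), lead)), drop = FALSE]
  write.table(cohort, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_tsv
#' @export
read_cohort_tsv <- function(path) {
  out <- read.delim(path, stringsAsFactors = FALSE)
  if ("centre" %in% names(out)) out$centre <- factor(out$centre)
  out
}

#' Read / write an instrument-definition table
#'
#' Fixed columns: `variant_id`, `effect_allele`, `other_allele`, `trait`.
#'
#' @param path file path.
#' @param instruments instrument data.frame.
#' @return the instrument data.frame (reader) or `path` (writer).
#' @export
read_instruments <- function(path) {
  out <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("variant_id", "effect_allele", "other_allele", "trait")
  if (!all(need %in% names(out)))
    stop("instrument file must have columns: ", paste(need, collapse = ", "))
  out
}

#' @rdname read_instruments
#' @export
write_instruments <- function(instruments, path) {
  write.table(instruments[, c("variant_id", "effect_allele", "other_allele",
                              "trait")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
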