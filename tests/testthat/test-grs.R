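test_that("dosage TSV and VCF writers round-trip through the readers", {
  cfg <- clean_config(40, seed = 130, n_variants_per_trait = c(5, 3, 3),
                      missing_genotype_rate = 0.1)
  g <- simulate_genotypes(cfg)
  td <- withr::local_tempdir()
  write_genotypes_tsv(g, file.path(td, "g.tsv"), file.path(td, "v.tsv"))
  g2 <- read_genotypes(file.path(td, "g.tsv"), "tsv", file.path(td, "v.tsv"))
  expect_equal(g2$dosages, g$dosages)
  expect_equal(g2$variants$effect_allele, g$variants$effect_allele)

  write_genotypes_vcf(g, file.path(td, "g.vcf"))
  g3 <- read_genotypes(file.path(td, "g.vcf"), "vcf", file.path(td, "v.tsv"))
  expect_equal(g3$dosages[g$sample_ids, g$variants$variant_id], g$dosages)
})

test_that("VCF GT fields convert to effect-allele dosage via the side-car", {
  td <- withr::local_tempdir()
  vcf <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", "S1", "S2"), collapse = "\t"),
           "1\t1\trs1\tG\tA\t.\tPASS\t.\tGT\t0/1\t1/1",
           "1\t2\trs2\tC\tT\t.\tPASS\t.\tGT\t0/0\t0/1")
  writeLines(vcf, file.path(td, "x.vcf"))
  # rs1 effect allele = ALT (A): dosage = ALT count; rs2 effect = REF (C)
  sidecar <- data.frame(variant_id = c("rs1", "rs2"),
                        effect_allele = c("A", "C"),
                        other_allele = c("G", "T"),
                        trait = "neuroticism")
  write.table(sidecar, file.path(td, "v.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  g <- read_genotypes(file.path(td, "x.vcf"), "vcf", file.path(td, "v.tsv"))
  expect_equal(unname(g$dosages[, "rs1"]), c(1, 2))
  expect_equal(unname(g$dosages[, "rs2"]), c(2, 1))
})

test_that("variant QC keeps a call rate of exactly 90% and drops below it", {
  n <- 100
  d <- matrix(1, n, 3)
  d[1:11, 1] <- NA  # call rate 0.89
  d[1:10, 2] <- NA  # call rate 0.90
  g <- toy_genotypes(d, traits = rep("neuroticism", 3))
  out <- variant_qc(g)
  expect_equal(out$variants$variant_id, c("v2", "v3"))
  expect_equal(attr(out, "removed_variants")$variant_id, "v1")
  expect_error(variant_qc(toy_genotypes(matrix(NA_real_, 10, 1),
                                        traits = "neuroticism")),
               "all variants")
})

test_that("a 74-variant panel with 4 low-quality variants retains exactly 70", {
  n <- 200
  d <- matrix(rbinom(n * 74, 2, 0.3), n, 74)
  d[1:(0.15 * n), 1:4] <- NA  # four variants at 85% call rate
  g <- toy_genotypes(d, traits = rep("education", 74))
  out <- variant_qc(g)
  expect_equal(ncol(out$dosages), 70)
})

test_that("effect-allele alignment complements other-allele orientation", {
  d <- rbind(c(0, 0), c(1, 2), c(2, 1))
  g <- genotype_matrix(d,
                       data.frame(variant_id = c("v1", "v2"),
                                  effect_allele = c("A", "C"),
                                  other_allele = c("G", "T"),
                                  eaf = c(0.5, 0.5),
                                  trait = "neuroticism"),
                       paste0("S", 1:3))
  instr <- data.frame(variant_id = c("v1", "v2"),
                      effect_allele = c("A", "T"),  # v2 flipped
                      other_allele = c("G", "C"),
                      trait = "neuroticism")
  out <- align_effect_alleles(g, instr)
  expect_equal(unname(out$dosages[, "v1"]), c(0, 1, 2))     # unchanged
  expect_equal(unname(out$dosages[, "v2"]), c(2, 0, 1))     # 2 - dosage
  expect_equal(out$variants$eaf[2], 0.5)

  # allele mismatch drops the variant; ambiguous strand drops in strict mode
  instr_bad <- data.frame(variant_id = "v1", effect_allele = "A",
                          other_allele = "C", trait = "neuroticism")
  expect_warning(out2 <- align_effect_alleles(g, instr_bad), "mismatch")
  expect_equal(ncol(out2$dosages), 0)
  g_at <- genotype_matrix(matrix(c(0, 1, 2), 3, 1),
                          data.frame(variant_id = "v9", effect_allele = "A",
                                     other_allele = "T", eaf = 0.5,
                                     trait = "neuroticism"),
                          paste0("S", 1:3))
  instr_at <- data.frame(variant_id = "v9", effect_allele = "A",
                         other_allele = "T", trait = "neuroticism")
  expect_warning(out3 <- align_effect_alleles(g_at, instr_at), "ambiguous")
  expect_equal(ncol(out3$dosages), 0)
  expect_equal(ncol(align_effect_alleles(g_at, instr_at,
                                         strict = FALSE)$dosages), 1)
})

test_that("the unweighted GRS is the risk-allele count with documented bounds", {
  d <- matrix(c(2, 1, 0, 2,
                0, 0, 0, 0), nrow = 2, byrow = TRUE)
  g <- toy_genotypes(d, traits = rep("neuroticism", 4))
  instr <- g$variants[, c("variant_id", "effect_allele", "other_allele", "trait")]
  res <- compute_unweighted_grs(g, instr, "neuroticism")
  expect_equal(unname(res$score), c(5, 0))
  expect_true(all(res$score >= 0 & res$score <= 2 * res$n_variants_used))
  expect_error(compute_unweighted_grs(g, instr, "education"), "empty")
})

test_that("GRS is invariant to variant and sample ordering", {
  cfg <- clean_config(50, seed = 131, n_variants_per_trait = c(8, 3, 3),
                      missing_genotype_rate = 0)
  sim <- simulate_cohort(cfg)
  s1 <- compute_unweighted_grs(sim$genotypes, sim$instruments, "neuroticism")$score
  shuffled <- sim$instruments[sample(nrow(sim$instruments)), ]
  s2 <- compute_unweighted_grs(sim$genotypes, shuffled, "neuroticism")$score
  expect_equal(s1, s2)
  expect_true(all(s1 == round(s1)))  # integer-valued without missingness
})

test_that("missing dosages impute as twice the in-sample allele frequency", {
  d <- matrix(c(2, 0, NA,
                1, 1, 1), ncol = 2)
  g <- toy_genotypes(d, traits = rep("neuroticism", 2))
  instr <- g$variants[, c("variant_id", "effect_allele", "other_allele", "trait")]
  res <- compute_unweighted_grs(g, instr, "neuroticism")
  expect_equal(unname(res$score[3]), 1 + 1)  # NA -> in-sample mean dosage 1
  res_drop <- compute_unweighted_grs(g, instr, "neuroticism", missing = "drop")
  expect_equal(unname(res_drop$score[3]), 1)
})

test_that("variance explained matches the incremental-R2 definition", {
  set.seed(132)
  n <- 2000
  score <- rbinom(n, 20, 0.3)
  age <- runif(n, 40, 70)
  sex <- rbinom(n, 1, 0.5)
  trait <- 0.05 * score + 0.01 * age + rnorm(n)
  ve <- variance_explained(score, trait, age, sex)
  full <- summary(lm(trait ~ score + age + sex))$r.squared
  base <- summary(lm(trait ~ age + sex))$r.squared
  expect_equal(ve$r2, full - base, tolerance = 1e-12)

  # independent trait: incremental R2 compatible with zero
  trait0 <- rnorm(n)
  ve0 <- variance_explained(score, trait0, age, sex)
  expect_lt(ve0$r2, 9 / n)  # chi-square_1 99.7% bound / n
  # exact linear function of the score with null covariate effects
  # (summary.lm warns about the perfect fit; that is the point of the case)
  ve1 <- suppressWarnings(variance_explained(score, 2 * score - 3, age, sex))
  expect_gt(ve1$r2, 0.999)
})
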