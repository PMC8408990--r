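toy_model <- function() {
  tibble::tibble(
    snp_id = c("s1", "s2", "s3", "s4"),
    effect_allele = c("A", "A", "A", "C"),
    other_allele = c("G", "C", "T", "T"),
    weight = c(0.5, -0.2, 0.3, 0.1))
}

test_that("allele harmonization enumerates the four cases", {
  gwas <- tibble::tibble(
    snp_id = c("s1", "s2", "s3"),
    effect_allele = c("A", "C", "A"),
    other_allele = c("G", "A", "T"),
    z = c(2, 1.5, -1), n = 1000)
  h <- harmonize_alleles(toy_model(), gwas)
  # s1 matched, s2 swapped (z negated), s3 A/T ambiguous, s4 absent
  expect_equal(h$snp_id, c("s1", "s2"))
  expect_equal(h$z, c(2, -1.5))
  counts <- attr(h, "counts")
  expect_equal(unname(counts[c("n_used", "n_flipped", "n_ambiguous",
                               "n_unmatched")]), c(2, 1, 1, 1))
})

test_that("identical allele frames pass through untouched", {
  m <- toy_model()[1:2, ]
  gwas <- dplyr::mutate(m[, 1:3], z = c(1, 2), n = 10)
  h <- harmonize_alleles(m, gwas)
  expect_equal(h$z, c(1, 2))
  expect_equal(attr(h, "counts")[["n_flipped"]], 0)
})

test_that("predicted variance is the quadratic form", {
  expect_equal(predicted_variance(0.5, matrix(1)), 0.25)
  expect_equal(predicted_variance(c(0.5, 0.5), diag(2)), 0.5)
  set.seed(2)
  S <- random_correlation(3)
  w <- c(0.2, -0.1, 0.4)
  direct <- 0
  for (j in 1:3) for (k in 1:3) direct <- direct + w[j] * w[k] * S[j, k]
  expect_equal(predicted_variance(w, S), direct, tolerance = 1e-12)
  expect_error(predicted_variance(c(1, 2), matrix(1)),
               class = "crosstwas_data_error")
})

test_that("gene z-score reduces correctly in closed-form cases", {
  # single SNP: scale cancels, Z_g = z
  one <- gene_zscore(0.7, matrix(2.5), 1.3)
  expect_equal(one$z_gene, 1.3)
  # two uncorrelated unit-variance SNPs, equal weights
  two <- gene_zscore(c(0.5, 0.5), diag(2), c(2, 2))
  expect_equal(two$z_gene, 4 / sqrt(2), tolerance = 1e-12)
  expect_equal(two$p, 2 * pnorm(-4 / sqrt(2)), tolerance = 1e-12)
  # untestable gene
  expect_error(gene_zscore(0, matrix(1), 1),
               class = "crosstwas_untestable_error")
})

test_that("effect back-conversion follows the per-SD convention", {
  e0 <- effect_and_ci(0, 0.5, 1e4)
  expect_equal(e0$or, 1)
  expect_equal(e0$or_low * e0$or_high, 1, tolerance = 1e-12)

  e1 <- effect_and_ci(1.96, 1, 1e4)
  expect_equal(e1$or_low, 1, tolerance = 1e-3)

  e2 <- effect_and_ci(-3, 0.5, 1e4)
  expect_equal(e2$effect, -0.06, tolerance = 1e-12)
  expect_equal(e2$or, exp(-0.06), tolerance = 1e-12)
  expect_equal(e2$or, 0.9418, tolerance = 1e-4)
  expect_equal(c(e2$ci_low, e2$ci_high), c(-0.06 - 0.0392, -0.06 + 0.0392),
               tolerance = 1e-12)
  expect_warning(effect_and_ci(1, 1, NA), "sample size")
})

test_that("summary associations are sign-equivariant and scale-invariant", {
  cfg <- sim_config(seed = 71, n_ref = 300, n_genes = 4,
                    n_snps_per_gene = 8, n_tissues = 2, h2_expr = 0.4,
                    causal_gene_frac = 0.5, gene_effect_sd = 0.05,
                    n_gwas = 20000, tissue_sample_fracs = c(0.9, 0.8))
  dat <- simulate_twas_data(cfg)
  db <- retain_models(train_expression_models(dat$panel, dat$tissues,
                                              n_lambda = 4, seed = 2))
  gm <- dat$panel$gene_meta
  cis <- setNames(lapply(seq_len(nrow(gm)), function(i)
    select_cis_snps(dat$panel$snp_meta, gm$tss[i], gm$tes[i], gm$chrom[i])),
    gm$gene_id)
  ld <- snp_covariance(dat$panel, cis)
  a1 <- twas_associate(db, dat$gwas, ld)
  expect_gt(nrow(a1), 0)
  expect_equal(a1$p, 2 * pnorm(-abs(a1$z_gene)), tolerance = 1e-12)
  expect_true(all(a1$ci_low <= a1$effect & a1$effect <= a1$ci_high))

  gw_neg <- dat$gwas
  gw_neg$z <- -gw_neg$z
  a2 <- twas_associate(db, gw_neg, ld)
  expect_equal(a2$z_gene, -a1$z_gene, tolerance = 1e-12)
  expect_equal(a2$p, a1$p, tolerance = 1e-12)

  db_scaled <- db
  db_scaled$weights$weight <- db_scaled$weights$weight * 7
  a3 <- twas_associate(db_scaled, dat$gwas, ld)
  expect_equal(a3$z_gene, a1$z_gene, tolerance = 1e-10)
})
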