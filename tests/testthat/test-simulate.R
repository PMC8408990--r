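test_that("genotype panels are deterministic and internally consistent", {
  cfg <- sim_config(seed = 7, n_ref = 120, n_genes = 4, n_snps_per_gene = 8,
                    n_tissues = 2, tissue_sample_fracs = c(0.8, 0.6))
  p1 <- simulate_genotypes(cfg)
  p2 <- simulate_genotypes(cfg)
  expect_identical(p1, p2)
  expect_true(all(p1$dosages >= 0 & p1$dosages <= 2))
  expect_false(anyDuplicated(p1$snp_meta$snp_id) > 0)
  expect_equal(p1$snp_meta$af, unname(colMeans(p1$dosages) / 2),
               tolerance = 1e-10)
  # every SNP polymorphic
  expect_true(all(apply(p1$dosages, 2, stats::sd) > 0))
})

test_that("invalid configurations name the offending field", {
  expect_error(sim_config(ld_rho = 1), "ld_rho",
               class = "crosstwas_config_error")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range",
               class = "crosstwas_config_error")
  expect_error(sim_config(n_causal_eqtl = 40, n_snps_per_gene = 10),
               "n_causal_eqtl", class = "crosstwas_config_error")
})

test_that("adjacent-SNP dosage correlation follows the AR(1) copula", {
  # independence case: empirical correlation near zero
  cfg0 <- sim_config(seed = 11, n_ref = 1500, n_genes = 3,
                     n_snps_per_gene = 10, ld_rho = 0)
  p0 <- simulate_genotypes(cfg0)
  X <- p0$dosages[, p0$snp_meta$snp_id[p0$snp_meta$block == 1]]
  r_adj <- sapply(seq_len(ncol(X) - 1), function(j) cor(X[, j], X[, j + 1]))
  expect_true(all(abs(r_adj) < 3 / sqrt(cfg0$n_ref)))

  # strong LD: matches the Monte-Carlo oracle for each adjacent pair
  cfg9 <- sim_config(seed = 12, n_ref = 2000, n_genes = 1,
                     n_snps_per_gene = 6, ld_rho = 0.9)
  p9 <- simulate_genotypes(cfg9)
  X9 <- p9$dosages
  maf <- colMeans(X9) / 2
  for (j in c(1, 3)) {
    mc <- oracle_ar1_dosage_cor(maf[j], maf[j + 1], 0.9)
    expect_equal(cor(X9[, j], X9[, j + 1]), mc, tolerance = 0.05)
  }
})

test_that("expression generator honours the variance decomposition", {
  cfg <- sim_config(seed = 21, n_ref = 2000, n_genes = 3,
                    n_snps_per_gene = 10, n_tissues = 2, h2_expr = 0.5,
                    n_causal_eqtl = 2, tissue_sample_fracs = c(1, 1))
  panel <- simulate_genotypes(cfg)
  se <- simulate_expression(panel, cfg)
  for (g in seq_len(3)) {
    w <- se$truth$true_weights[[g]][, 1]
    score <- drop(panel$dosages[, names(w)] %*% w)
    y <- se$tissues[[1]]$expression[, g]
    r2 <- summary(lm(y ~ score))$r.squared
    expect_equal(r2, 0.5, tolerance = 0.05)
  }
  # expression columns centred
  expect_true(all(abs(colMeans(se$tissues[[1]]$expression)) < 1e-8))
})

test_that("degenerate expression settings behave as specified", {
  cfg0 <- sim_config(seed = 22, n_ref = 100, n_genes = 2,
                     n_snps_per_gene = 6, n_tissues = 2, h2_expr = 0,
                     tissue_sample_fracs = c(1, 0.7))
  panel <- simulate_genotypes(cfg0)
  se <- simulate_expression(panel, cfg0)
  expect_true(all(sapply(se$truth$true_weights, function(w) all(w == 0))))

  cfg1 <- sim_config(seed = 23, n_ref = 100, n_genes = 2,
                     n_snps_per_gene = 6, n_tissues = 3,
                     cross_tissue_cor = 1,
                     tissue_sample_fracs = c(1, 1, 1))
  se1 <- simulate_expression(simulate_genotypes(cfg1), cfg1)
  for (w in se1$truth$true_weights) {
    expect_equal(w[, 1], w[, 2])
    expect_equal(w[, 1], w[, 3])
  }
})

test_that("null GWAS z-scores are calibrated and deterministic", {
  cfg <- sim_config(seed = 31, n_ref = 600, n_genes = 200,
                    n_snps_per_gene = 10, n_tissues = 1, ld_rho = 0,
                    causal_gene_frac = 0, tissue_sample_fracs = 1)
  dat <- simulate_twas_data(cfg)
  z <- dat$gwas$z
  expect_true(all(dat$truth$gene_trait_effects == 0))
  frac <- mean(abs(z) > 1.96)
  se3 <- 3 * sqrt(0.05 * 0.95 / length(z))
  expect_lt(abs(frac - 0.05), se3)
  # determinism
  dat2 <- simulate_twas_data(cfg)
  expect_identical(dat$gwas$z, dat2$gwas$z)
})

test_that("mean Z at a causal SNP matches sqrt(n) * gamma over replicates", {
  devs <- sapply(1:200, function(s) {
    cfg <- sim_config(seed = 1000 + s, n_ref = 150, n_genes = 1,
                      n_snps_per_gene = 4, n_tissues = 1, ld_rho = 0,
                      n_causal_eqtl = 1, h2_expr = 0.5,
                      causal_gene_frac = 1, gene_effect_sd = 0.05,
                      n_gwas = 10000, tissue_sample_fracs = 1)
    dat <- simulate_twas_data(cfg)
    snp <- dat$truth$causal_eqtl[[1]]
    idx <- match(snp, dat$gwas$snp_id)
    dat$gwas$z[idx] -
      sqrt(cfg$n_gwas) * dat$truth$marginal_snp_effects[snp]
  })
  # each deviation is N(0,1) noise; its mean over 200 draws is within 3 SE
  expect_lt(abs(mean(devs)), 3 / sqrt(200))
})

test_that("doubling the gene effect scale doubles the marginal effects", {
  base <- list(seed = 41, n_ref = 200, n_genes = 4, n_snps_per_gene = 6,
               n_tissues = 1, causal_gene_frac = 1,
               tissue_sample_fracs = 1)
  d1 <- simulate_twas_data(do.call(sim_config,
                                   c(base, gene_effect_sd = 0.02)))
  d2 <- simulate_twas_data(do.call(sim_config,
                                   c(base, gene_effect_sd = 0.04)))
  g1 <- d1$truth$marginal_snp_effects
  g2 <- d2$truth$marginal_snp_effects
  expect_equal(g2, 2 * g1, tolerance = 1e-12)
})

test_that("shared-block mode puts gene pairs on one block with disjoint
           causal sets", {
  cfg <- sim_config(seed = 51, n_ref = 200, n_genes = 4,
                    n_snps_per_gene = 12, n_tissues = 1,
                    n_causal_eqtl = 3, shared_blocks = TRUE,
                    tissue_sample_fracs = 1)
  panel <- simulate_genotypes(cfg)
  expect_equal(panel$gene_meta$block, c(1, 1, 2, 2))
  se <- simulate_expression(panel, cfg)
  expect_length(intersect(se$truth$causal_eqtl[[1]],
                          se$truth$causal_eqtl[[2]]), 0)
  # both genes' cis windows cover the shared block
  for (g in 1:2) {
    cis <- select_cis_snps(panel$snp_meta, panel$gene_meta$tss[g],
                           panel$gene_meta$tes[g], chrom = "1")
    expect_setequal(cis, panel$snp_meta$snp_id[panel$snp_meta$block == 1])
  }
})
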