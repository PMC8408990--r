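test_that("cis-window selection uses closed 1-based boundaries", {
  meta <- tibble::tibble(
    snp_id = c("a", "b", "c", "d"), chrom = "1",
    pos = c(4989999, 4990000, 5020000, 5020001))
  got <- select_cis_snps(meta, tss = 5e6, tes = 5010000, chrom = "1",
                         window = 1e4)
  expect_identical(got, c("b", "c"))
  # exact boundary SNP included, one bp outside excluded
  meta2 <- tibble::tibble(snp_id = c("x", "y"), chrom = "1",
                          pos = c(4e6, 4e6 - 1))
  expect_identical(select_cis_snps(meta2, 5e6, 5e6, "1", 1e6), "x")
})

test_that("single-pair grids and duplicated pairs resolve deterministically", {
  inst <- make_sgl_instance(n = 60, p = 5, d = 2, seed = 41)
  g1 <- tibble::tibble(lambda1 = 0.1, lambda2 = 0.05)
  t1 <- tune_consistent_grid(inst$X, inst$Y, g1, seed = 1)
  expect_equal(t1$lambda1, 0.1)
  expect_true(all(sapply(t1$oof, function(o) all(is.finite(o)))))

  gdup <- tibble::tibble(lambda1 = c(0.1, 0.1), lambda2 = c(0.05, 0.05))
  tdup <- tune_consistent_grid(inst$X, inst$Y, gdup, seed = 1)
  expect_equal(tdup$selected, 1L)
})

test_that("pure-noise expression selects the largest penalties", {
  hits <- sapply(1:50, function(s) {
    set.seed(6000 + s)
    n <- 80; p <- 8; d <- 2
    X <- lapply(1:d, function(t) matrix(rnorm(n * p), n, p))
    Xs <- lapply(X, function(x) scale(x)[, , drop = FALSE])
    Y <- lapply(1:d, function(t) { y <- rnorm(n); y - mean(y) })
    grid <- make_lambda_grid(Xs, Y, n_lambda1 = 5, n_lambda2 = 3)
    tn <- tune_consistent_grid(X, Y, grid, seed = s)
    ladder1 <- sort(unique(grid$lambda1), decreasing = TRUE)
    tn$lambda1 == ladder1[1]
  })
  expect_gte(mean(hits), 0.8)
})

test_that("performance evaluation matches the t-distribution oracle", {
  # exact prediction
  x <- rnorm(20)
  perf <- evaluate_performance(x, x)
  expect_equal(perf$r, 1)
  expect_lt(perf$p, 1e-12)

  # constant predictions are the degenerate case
  perf0 <- evaluate_performance(rep(0, 10), rnorm(10))
  expect_equal(perf0$r, 0)
  expect_equal(perf0$p, 1)

  # r = 0.1 at n = 205: p ~ 0.15, failing retention despite r >= 0.1
  set.seed(8)
  a <- rnorm(205); b <- rnorm(205)
  ac <- a - mean(a)
  bc <- b - mean(b)
  bc <- bc - sum(bc * ac) / sum(ac^2) * ac    # centred, orthogonal to ac
  obs <- 0.1 * ac / sqrt(sum(ac^2)) + sqrt(0.99) * bc / sqrt(sum(bc^2))
  perf1 <- evaluate_performance(a, obs)
  t_oracle <- 0.1 * sqrt(203 / (1 - 0.01))
  p_oracle <- 2 * pt(-t_oracle, df = 203)
  expect_equal(perf1$r, 0.1, tolerance = 1e-8)
  expect_equal(perf1$p, p_oracle, tolerance = 1e-8)
  expect_gt(perf1$p, 0.05)
  expect_equal(p_oracle, 0.15, tolerance = 0.03)

  expect_error(evaluate_performance(1:4, 1:5),
               class = "crosstwas_data_error")
})

test_that("retention applies both boundaries as written", {
  db <- structure(list(
    weights = tibble::tibble(
      gene = c("g1", "g2", "g3"), tissue = "t1",
      snp_id = "s", chrom = "1", pos = 1,
      effect_allele = "A", other_allele = "G", weight = 1),
    extra = tibble::tibble(
      gene = c("g1", "g2", "g3"), tissue = "t1", n_snps = 1L,
      r = c(0.1, 0.1, -0.5), p = c(0.04, 0.06, 1e-9),
      n_eval = 100L, r2 = c(0.01, 0.01, 0),
      lambda1 = 0.1, lambda2 = 0.1)), class = "weight_db")
  kept <- retain_models(db)
  expect_equal(kept$extra$gene, "g1")
  expect_equal(nrow(kept$weights), 1)

  db2 <- db
  db2$extra$r <- c(0.30, 0.099, 0.2)
  db2$extra$p <- c(1e-4, 1e-6, 0.2)
  kept2 <- retain_models(db2)
  expect_equal(kept2$extra$gene, "g1")
})

test_that("trained weight databases recover strong cis signals", {
  cfg <- sim_config(seed = 61, n_ref = 400, n_genes = 3,
                    n_snps_per_gene = 8, n_tissues = 2, h2_expr = 0.5,
                    n_causal_eqtl = 1, tissue_sample_fracs = c(0.9, 0.8))
  dat <- simulate_twas_data(cfg)
  db_all <- train_expression_models(dat$panel, dat$tissues, n_lambda = 4,
                                    seed = 5)
  expect_equal(nrow(db_all$extra), 6)
  db <- retain_models(db_all)
  expect_gt(nrow(db$extra), 0)
  # weights only for retained models, nonzero, alleles sane
  expect_true(all(db$weights$weight != 0))
  expect_true(all(db$weights$effect_allele != db$weights$other_allele))
  # every retained model clears the r^2 floor implied by r >= 0.1
  counts <- attr(db, "tissue_counts")
  expect_true(all(counts$n_retained == counts$n_r2_ge_0.01))
  expect_true(all(db$extra$r2 >= 0.01))
})

test_that("out-of-fold r sits below in-sample r of a full-data refit", {
  set.seed(99)
  n <- 100; p <- 8; d <- 2
  wins <- sapply(1:15, function(s) {
    set.seed(7000 + s)
    X <- lapply(1:d, function(t) matrix(rnorm(n * p), n, p))
    Y <- lapply(1:d, function(t) rnorm(n))   # pure noise
    Xs <- lapply(X, function(x) scale(x)[, , drop = FALSE])
    lmax <- sgl_lambda_max(Xs, Y)
    pair <- tibble::tibble(lambda1 = 0.1 * lmax, lambda2 = 0.1 * lmax)
    tn <- tune_consistent_grid(X, Y, pair, seed = s)
    r_oof <- mean(sapply(1:d, function(t)
      evaluate_performance(tn$oof[[t]], Y[[t]])$r))
    r_in <- mean(insample_performance(X, Y, pair$lambda1, pair$lambda2)$r)
    r_in > r_oof
  })
  expect_gte(mean(wins), 0.8)
})
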