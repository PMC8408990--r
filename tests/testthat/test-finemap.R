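test_that("predicted-expression correlation matches the double-sum oracle", {
  S <- matrix(c(1, 0.4, 0.4, 1), 2, dimnames = list(c("s1", "s2"),
                                                    c("s1", "s2")))
  w <- list(gA = c(s1 = 0.5), gB = c(s1 = 0.2, s2 = 0.7))
  om <- predicted_expression_correlation(w, S)
  expect_equal(om["gA", "gA"], 1)
  # brute-force double sum
  wA <- c(0.5, 0); wB <- c(0.2, 0.7)
  num <- 0
  for (j in 1:2) for (k in 1:2) num <- num + wA[j] * wB[k] * S[j, k]
  den <- sqrt(sum(outer(wA, wA) * S)) * sqrt(sum(outer(wB, wB) * S))
  expect_equal(om["gA", "gB"], num / den, tolerance = 1e-12)

  # disjoint SNPs under block-diagonal covariance: zero correlation
  S2 <- diag(2); dimnames(S2) <- list(c("s1", "s2"), c("s1", "s2"))
  w2 <- list(gA = c(s1 = 1), gB = c(s2 = 1))
  expect_equal(predicted_expression_correlation(w2, S2)["gA", "gB"], 0)

  # zero-variance gene excluded with a reason
  w3 <- list(gA = c(s1 = 1), gB = c(s2 = 0))
  om3 <- predicted_expression_correlation(w3, S2)
  expect_equal(attr(om3, "excluded"), "gB")
  expect_equal(rownames(om3), "gA")
})

test_that("configuration Bayes factors match closed forms and densities", {
  expect_equal(config_log_bf(integer(0), c(1, 2), diag(2)), 0)
  # single gene, identity omega, z = 0: -log(1+v)/2
  v <- 40
  lbf0 <- config_log_bf(1, 0, matrix(1), prior_var = v, ridge = 0)
  expect_equal(lbf0, -0.5 * log(1 + v), tolerance = 1e-12)
  expect_lt(lbf0, 0)
  # single gene, z = 3: density-ratio oracle and printed value
  lbf3 <- config_log_bf(1, 3, matrix(1), prior_var = v, ridge = 0)
  oracle <- oracle_dmvnorm_log(3, matrix(1 + v)) -
    oracle_dmvnorm_log(3, matrix(1))
  expect_equal(lbf3, oracle, tolerance = 1e-10)
  expect_equal(exp(lbf3), 12.6, tolerance = 0.01)
})

test_that("posterior enumeration matches exhaustive hand enumeration", {
  om <- matrix(c(1, 0.3, 0.3, 1), 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  region <- list(region_id = "r", genes = c("a", "b"),
                 twas_z = c(2.5, -1), omega = om, prior_prob = 1e-3,
                 prior_var = 40, max_causal = 2, ridge = 0.1)
  res <- enumerate_posterior(region)
  oracle <- oracle_finemap_pips(c(2.5, -1), om)
  expect_equal(res$pips$pip, oracle, tolerance = 1e-10)
  expect_equal(sum(res$configurations$posterior), 1, tolerance = 1e-8)

  # z = 0 everywhere: data down-weight causality below the prior
  res0 <- enumerate_posterior(list(region_id = "r0", genes = c("a", "b"),
                                   twas_z = c(0, 0), omega = om))
  expect_true(all(res0$pips$pip < 1e-3))

  # duplicated gene: symmetric PIPs
  om1 <- matrix(1, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  resd <- enumerate_posterior(list(region_id = "rd", genes = c("a", "b"),
                                   twas_z = c(2, 2), omega = om1))
  expect_equal(resd$pips$pip[1], resd$pips$pip[2], tolerance = 1e-12)
})

test_that("PIP grows with |z| in a single-gene region", {
  pips <- sapply(c(0, 1, 2, 3, 4, 6), function(z)
    enumerate_posterior(list(region_id = "r", genes = "a", twas_z = z,
                             omega = matrix(1, dimnames = list("a", "a"))
                             ))$pips$pip)
  expect_true(all(diff(pips) > 0))
})

test_that("credible sets honour the >= stopping convention", {
  tbl <- tibble::tibble(gene = c("g1", "g2", "g3"),
                        pip = c(0.9, 0.09, 0.01))
  expect_identical(credible_set(tbl, 0.9), c(TRUE, FALSE, FALSE))
  # equal PIPs across 10 genes: 9 needed
  tbl10 <- tibble::tibble(gene = sprintf("g%02d", 1:10), pip = rep(0.1, 10))
  expect_equal(sum(credible_set(tbl10, 0.9)), 9)
  # single gene
  expect_true(credible_set(tibble::tibble(gene = "g", pip = 0.2), 0.9))
  expect_warning(
    flags <- credible_set(tibble::tibble(gene = "g", pip = 0)),
    "empty")
  expect_false(any(flags))
})

test_that("regions are connected components above the threshold", {
  om <- diag(4)
  om[1, 2] <- om[2, 1] <- 0.3
  om[3, 4] <- om[4, 3] <- -0.2
  dimnames(om) <- list(letters[1:4], letters[1:4])
  reg <- build_regions(om)
  expect_equal(reg[["a"]], reg[["b"]])
  expect_equal(reg[["c"]], reg[["d"]])
  expect_false(reg[["a"]] == reg[["c"]])
  # chromosome boundaries are never crossed
  reg2 <- build_regions(om, chrom = c(a = "1", b = "2", c = "3", d = "3"))
  expect_false(reg2[["a"]] == reg2[["b"]])
})
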