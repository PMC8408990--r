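#' Simulate an LD-structured genotype reference panel
#'
#' Draws dosages for `n_genes` cis SNP blocks. Within a block, each of the
#' two haplotypes per individual is generated from a latent Gaussian AR(1)
#' copula with adjacent-SNP correlation `ld_rho`; the allele indicator is 1
#' when the latent value falls below the MAF quantile, and the dosage is the
#' sum of the two haplotypes. MAFs are uniform on `maf_range`. Blocks are
#' mutually independent and placed 4 Mb apart on one chromosome so that
#' 1 Mb cis windows never cross blocks; with `shared_blocks = TRUE`
#' consecutive gene pairs sit on a single block with overlapping windows.
#' Monomorphic columns (possible at small `n_ref`) are redrawn so every SNP
#' is polymorphic.
#'
#' @param cfg A [sim_config()].
#' @return A `reference_panel`: list with `dosages` (individuals x SNPs
#'   matrix, values in \[0, 2\]), `snp_meta` (tibble: snp_id, chrom, pos,
#'   effect_allele, other_allele, af, block), `gene_meta` (tibble: gene_id,
#'   chrom, tss, tes, block), `sample_ids`.
#' @export
simulate_genotypes <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  G <- cfg$n_genes
  p <- cfg$n_snps_per_gene
  n <- cfg$n_ref

  if (cfg$shared_blocks) {
    block_of_gene <- ceiling(seq_len(G) / 2)
  } else {
    block_of_gene <- seq_len(G)
  }
  n_blocks <- max(block_of_gene)

  gene_meta <- purrr::map_dfr(seq_len(G), function(g) {
    b <- block_of_gene[g]
    origin <- (b - 1) * 4e6
    if (cfg$shared_blocks && sum(block_of_gene == b) == 2L) {
      first <- which(block_of_gene == b)[1] == g
      tss <- origin + if (first) 1.40e6 else 2.10e6
    } else {
      tss <- origin + 1e6
    }
    tibble(gene_id = sprintf("gene_%03d", g), chrom = "1",
           tss = tss, tes = tss + 1e4, block = b)
  })

  allele_pairs <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C",
                           "G", "A", "C", "A", "G", "T", "C", "T"),
                         ncol = 2, byrow = TRUE)

  snp_meta_list <- vector("list", n_blocks)
  dosage_list <- vector("list", n_blocks)
  for (b in seq_len(n_blocks)) {
    origin <- (b - 1) * 4e6
    pos <- round(seq(origin + 1.5e6, origin + 2.0e6, length.out = p))
    maf <- runif(p, cfg$maf_range[1], cfg$maf_range[2])
    X <- draw_block_dosages(n, p, maf, cfg$ld_rho)
    pair_idx <- sample.int(nrow(allele_pairs), p, replace = TRUE)
    ids <- sprintf("snp_b%03d_%03d", b, seq_len(p))
    colnames(X) <- ids
    snp_meta_list[[b]] <- tibble(
      snp_id = ids, chrom = "1", pos = pos,
      effect_allele = allele_pairs[pair_idx, 1],
      other_allele = allele_pairs[pair_idx, 2],
      af = unname(colMeans(X)) / 2, block = b)
    dosage_list[[b]] <- X
  }

  dosages <- do.call(cbind, dosage_list)
  sample_ids <- sprintf("ind_%04d", seq_len(n))
  rownames(dosages) <- sample_ids

  structure(list(dosages = dosages,
                 snp_meta = dplyr::bind_rows(snp_meta_list),
                 gene_meta = gene_meta,
                 sample_ids = sample_ids),
            class = "reference_panel")
}

# Two AR(1)-copula haplotypes per individual; redraw monomorphic columns.
draw_block_dosages <- function(n, p, maf, rho) {
  one_hap <- function() {
    Z <- matrix(rnorm(n * p), n, p)
    if (rho > 0 && p > 1) {
      for (j in 2:p) Z[, j] <- rho * Z[, j - 1] + sqrt(1 - rho^2) * Z[, j]
    }
    t(t(Z) < qnorm(maf)) * 1
  }
  X <- one_hap() + one_hap()
  bad <- which(apply(X, 2, function(x) min(x) == max(x)))
  tries <- 0L
  while (length(bad) > 0 && tries < 100L) {
    # independent redraw of offending columns keeps every SNP polymorphic
    for (j in bad) {
      h <- (rnorm(n) < qnorm(maf[j])) + (rnorm(n) < qnorm(maf[j]))
      X[, j] <- as.numeric(h)
    }
    bad <- which(apply(X, 2, function(x) min(x) == max(x)))
    tries <- tries + 1L
  }
  X
}

#' @export
print.reference_panel <- function(x, ...) {
  cat(sprintf("<reference_panel> %d individuals x %d SNPs, %d genes\n",
              nrow(x$dosages), ncol(x$dosages), nrow(x$gene_meta)))
  invisible(x)
}

#' Simulate multi-tissue expression with a shared cis-eQTL architecture
#'
#' For each gene, `n_causal_eqtl` SNPs are drawn from its cis block; each
#' causal SNP's per-tissue effect vector comes from a multivariate normal
#' with exchangeable correlation `cross_tissue_cor`. Within each tissue the
#' genetic score over that tissue's donor subset is rescaled to variance
#' `h2_expr` exactly and independent Gaussian noise of variance
#' `1 - h2_expr` is added, so the variance decomposition is exact by
#' construction; columns are mean-centred (residualized scale). Donor
#' subsets are drawn without replacement and overlap across tissues. Causal
#' genes (fraction `causal_gene_frac`) receive trait effects drawn from
#' `N(0, gene_effect_sd^2)`; all other genes have effect exactly 0.
#'
#' @param panel A `reference_panel` from [simulate_genotypes()].
#' @param cfg The matching [sim_config()].
#' @return A list with `tissues` (list of `tissue_expression`: tissue id,
#'   `samples`, `expression` matrix samples x genes, `n_t`) and `truth`
#'   (list: `true_weights` gene -> SNPs x tissues matrix on the dosage
#'   scale, `causal_eqtl` gene -> SNP ids, `causal_genes`,
#'   `gene_trait_effects` named vector).
#' @export
simulate_expression <- function(panel, cfg) {
  validate_sim_config(cfg)
  stopifnot(inherits(panel, "reference_panel"))
  if (cfg$n_causal_eqtl > cfg$n_snps_per_gene)
    abort("n_causal_eqtl exceeds n_snps_per_gene",
          class = "crosstwas_config_error")
  set.seed(cfg$seed + 1L)

  G <- cfg$n_genes
  d <- cfg$n_tissues
  n <- length(panel$sample_ids)
  genes <- panel$gene_meta$gene_id

  tissue_samples <- lapply(seq_len(d), function(t) {
    m <- max(3L, round(cfg$tissue_sample_fracs[t] * n))
    sort(sample.int(n, min(m, n)))
  })

  # exchangeable cross-tissue effect correlation via a shared component:
  # b_t = sqrt(rho) * u + sqrt(1 - rho) * e_t, valid at rho = 1 exactly
  ctc <- cfg$cross_tissue_cor

  used_in_block <- list()
  true_weights <- setNames(vector("list", G), genes)
  causal_eqtl <- setNames(vector("list", G), genes)
  expr <- lapply(seq_len(d), function(t)
    matrix(0, length(tissue_samples[[t]]), G,
           dimnames = list(panel$sample_ids[tissue_samples[[t]]], genes)))

  for (g in seq_len(G)) {
    gm <- panel$gene_meta[g, ]
    snp_ids <- panel$snp_meta$snp_id[panel$snp_meta$block == gm$block]
    p <- length(snp_ids)
    bkey <- as.character(gm$block)
    avail <- setdiff(seq_len(p), used_in_block[[bkey]])
    idx <- sort(sample(avail, cfg$n_causal_eqtl))
    if (cfg$shared_blocks) used_in_block[[bkey]] <- c(used_in_block[[bkey]], idx)

    B <- matrix(0, p, d, dimnames = list(snp_ids, NULL))
    if (cfg$h2_expr > 0) {
      shared <- rnorm(cfg$n_causal_eqtl)
      idio <- matrix(rnorm(cfg$n_causal_eqtl * d), cfg$n_causal_eqtl, d)
      B[idx, ] <- sqrt(ctc) * shared + sqrt(1 - ctc) * idio
    }
    X <- panel$dosages[, snp_ids, drop = FALSE]
    score <- X %*% B                       # n x d genetic scores
    TW <- matrix(0, p, d, dimnames = list(snp_ids, NULL))

    for (t in seq_len(d)) {
      st <- tissue_samples[[t]]
      # panel-wide scaling: variance share is h2_expr in the population
      # sense, and perfectly shared effects stay identical across tissues
      v_t <- stats::var(score[, t])
      sc <- if (cfg$h2_expr > 0 && v_t > 0) sqrt(cfg$h2_expr / v_t) else 0
      TW[, t] <- B[, t] * sc
      e <- score[st, t] * sc + rnorm(length(st), 0, sqrt(1 - cfg$h2_expr))
      expr[[t]][, g] <- e - mean(e)
    }
    true_weights[[g]] <- TW
    causal_eqtl[[g]] <- if (cfg$h2_expr > 0) snp_ids[idx] else character(0)
  }

  n_causal <- round(cfg$causal_gene_frac * G)
  causal_genes <- if (n_causal > 0) sort(sample(genes, n_causal)) else character(0)
  eff <- setNames(numeric(G), genes)
  if (n_causal > 0) eff[causal_genes] <- rnorm(n_causal, 0, cfg$gene_effect_sd)

  tissues <- lapply(seq_len(d), function(t) {
    structure(list(tissue = sprintf("tissue_%02d", t),
                   samples = panel$sample_ids[tissue_samples[[t]]],
                   expression = expr[[t]],
                   n_t = length(tissue_samples[[t]])),
              class = "tissue_expression")
  })
  truth <- list(true_weights = true_weights, causal_eqtl = causal_eqtl,
                causal_genes = causal_genes, gene_trait_effects = eff)
  list(tissues = tissues, truth = truth)
}

#' Rank-based inverse normal transform with covariate residualization
#'
#' Per column: average-rank inverse normal scores
#' `qnorm((rank - 3/8) / (n + 1/4))`, then least-squares residualization on
#' the covariates. An intercept is prepended unless the constant vector
#' already lies in the covariate span, so output columns have zero
#' correlation with every covariate.
#'
#' @param raw Numeric matrix, samples x genes.
#' @param covariates Numeric matrix, samples x covariates (aligned rows).
#' @return Residual matrix, same shape and dimnames as `raw`.
#' @export
preprocess_expression <- function(raw, covariates) {
  raw <- as.matrix(raw)
  covariates <- as.matrix(covariates)
  if (nrow(raw) != nrow(covariates))
    abort("rows of `raw` and `covariates` must be aligned",
          class = "crosstwas_data_error")
  qr_cov <- qr(covariates)
  if (qr_cov$rank < ncol(covariates)) {
    bad <- qr_cov$pivot[(qr_cov$rank + 1L):ncol(covariates)]
    nm <- colnames(covariates) %||% as.character(seq_len(ncol(covariates)))
    abort(sprintf("covariate matrix is rank-deficient; collinear columns: %s",
                  paste(nm[bad], collapse = ", ")),
          class = "crosstwas_data_error")
  }
  n <- nrow(raw)
  design <- cbind(`(Intercept)` = 1, covariates)
  if (qr(design)$rank < ncol(design)) design <- covariates

  int <- apply(raw, 2, function(x) {
    r <- rank(x, ties.method = "average")
    qnorm((r - 3 / 8) / (n + 1 / 4))
  })
  int <- matrix(int, nrow = n, dimnames = dimnames(raw))
  res <- int - design %*% qr.coef(qr(design), int)
  dimnames(res) <- dimnames(raw)
  res
}

#' Simulate GWAS summary statistics consistent with panel LD
#'
#' Summary mode (default): per SNP block, the per-SNP trait effect on the
#' dosage scale is the across-tissue mean of the true eQTL weights times the
#' gene's trait effect (summed over genes on the block); marginal
#' standardized effects are `gamma = R b_std` with `R` the panel dosage
#' correlation, and `Z ~ MVN(sqrt(n_gwas) * gamma, R)`. Individual mode
#' draws a fresh cohort of `n_gwas` genotypes from the panel allele
#' frequencies and the same AR(1) copula, builds the quantitative trait from
#' the genetic expression scores plus unit noise, and computes per-SNP
#' marginal regression Z statistics; the cohort is attached as attribute
#' `"cohort"` for oracle use.
#'
#' @param panel A `reference_panel`.
#' @param truth Truth bundle from [simulate_expression()].
#' @param cfg The matching [sim_config()].
#' @param method `"summary"` (direct summary-level draw) or `"individual"`.
#' @return A tibble (class `gwas_summary`): snp_id, effect_allele,
#'   other_allele, z, n; attribute `"marginal_snp_effects"` holds gamma.
#' @export
simulate_gwas <- function(panel, truth, cfg,
                          method = c("summary", "individual")) {
  method <- match.arg(method)
  validate_sim_config(cfg)
  set.seed(cfg$seed + 2L)

  sm <- panel$snp_meta
  blocks <- split(seq_len(nrow(sm)), sm$block)
  eff <- truth$gene_trait_effects

  # dosage-scale per-SNP trait effects, by block
  b_dos <- setNames(numeric(nrow(sm)), sm$snp_id)
  for (g in names(truth$true_weights)) {
    if (eff[[g]] == 0) next
    w <- rowMeans(truth$true_weights[[g]])
    b_dos[names(w)] <- b_dos[names(w)] + eff[[g]] * w
  }

  if (method == "summary") {
    z <- numeric(nrow(sm))
    gamma <- numeric(nrow(sm))
    for (bi in names(blocks)) {
      idx <- blocks[[bi]]
      X <- panel$dosages[, idx, drop = FALSE]
      R <- stats::cor(X)
      sds <- apply(X, 2, stats::sd)
      L <- tryCatch(chol(R), error = function(e) {
        tryCatch(chol(R + diag(1e-6, nrow(R))), error = function(e2) {
          abort(sprintf(
            "LD matrix for block %s not positive definite after regularization",
            bi), class = "crosstwas_numeric_error")
        })
      })
      gma <- drop(R %*% (b_dos[idx] * sds))
      z[idx] <- sqrt(cfg$n_gwas) * gma + drop(crossprod(L, rnorm(length(idx))))
      gamma[idx] <- gma
    }
  } else {
    Xc <- cohort_genotypes(panel, cfg)
    y <- rnorm(cfg$n_gwas)
    for (g in names(truth$true_weights)) {
      if (eff[[g]] == 0) next
      w <- rowMeans(truth$true_weights[[g]])
      y <- y + eff[[g]] * drop(Xc[, names(w), drop = FALSE] %*% w)
    }
    r <- drop(stats::cor(Xc, y))
    z <- r * sqrt((cfg$n_gwas - 2) / pmax(1 - r^2, 1e-12))
    gamma <- r
  }

  out <- tibble(snp_id = sm$snp_id,
                effect_allele = sm$effect_allele,
                other_allele = sm$other_allele,
                z = unname(z), n = cfg$n_gwas)
  class(out) <- c("gwas_summary", class(out))
  attr(out, "marginal_snp_effects") <- setNames(unname(gamma), sm$snp_id)
  if (method == "individual") attr(out, "cohort") <- list(X = Xc, y = y)
  out
}

# fresh cohort from panel allele frequencies + the same AR(1) copula
cohort_genotypes <- function(panel, cfg) {
  sm <- panel$snp_meta
  out <- matrix(0, cfg$n_gwas, nrow(sm),
                dimnames = list(NULL, sm$snp_id))
  for (b in unique(sm$block)) {
    idx <- which(sm$block == b)
    maf <- pmin(pmax(sm$af[idx], 1e-3), 1 - 1e-3)
    out[, idx] <- draw_block_dosages(cfg$n_gwas, length(idx), maf, cfg$ld_rho)
  }
  out
}

#' Simulate a complete synthetic study
#'
#' Convenience driver: genotypes, expression + truth, and GWAS summary
#' statistics in one call, with the marginal SNP effects folded into the
#' truth bundle.
#'
#' @inheritParams simulate_gwas
#' @param cfg A [sim_config()].
#' @return List with `panel`, `tissues`, `truth`, `gwas`.
#' @export
simulate_twas_data <- function(cfg, method = "summary") {
  panel <- simulate_genotypes(cfg)
  se <- simulate_expression(panel, cfg)
  gwas <- simulate_gwas(panel, se$truth, cfg, method = method)
  truth <- se$truth
  truth$marginal_snp_effects <- attr(gwas, "marginal_snp_effects")
  list(panel = panel, tissues = se$tissues, truth = truth, gwas = gwas)
}
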