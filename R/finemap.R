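#' Correlation of predicted expression between genes
#'
#' On a shared SNP frame (union of the models' SNPs, weights zero-padded),
#' `Omega_ij = w_i' Sigma w_j / (sigma_i sigma_j)`, clipped to \[-1, 1\].
#' Genes with `sigma = 0` are excluded with a logged reason.
#'
#' @param weights Named list gene -> named weight vector (names are SNP
#'   ids).
#' @param sigma SNP covariance matrix over the union frame (dimnames must
#'   cover all weight names).
#' @return Gene x gene correlation matrix; attribute `"excluded"` lists
#'   zero-variance genes.
#' @export
predicted_expression_correlation <- function(weights, sigma) {
  sigma <- as.matrix(sigma)
  snps <- rownames(sigma)
  W <- vapply(weights, function(w) {
    v <- setNames(numeric(length(snps)), snps)
    v[names(w)] <- w
    v
  }, numeric(length(snps)))
  V <- crossprod(W, sigma %*% W)         # w_i' Sigma w_j
  sd_g <- sqrt(pmax(diag(V), 0))
  excluded <- names(weights)[sd_g < 1e-8]
  keep <- sd_g >= 1e-8
  V <- V[keep, keep, drop = FALSE]
  sd_g <- sd_g[keep]
  omega <- V / tcrossprod(sd_g)
  omega[omega > 1] <- 1
  omega[omega < -1] <- -1
  diag(omega) <- 1
  dimnames(omega) <- list(names(weights)[keep], names(weights)[keep])
  attr(omega, "excluded") <- excluded
  omega
}

#' Group genes into fine-mapping regions
#'
#' Regions are connected components of the graph joining genes (within a
#' chromosome) whose predicted-expression correlation exceeds `threshold`
#' in absolute value.
#'
#' @param omega Gene x gene correlation matrix (dimnames = gene ids).
#' @param chrom Optional named chromosome vector per gene; genes on
#'   different chromosomes are never joined.
#' @param threshold Absolute-correlation threshold.
#' @return Named integer vector: region id per gene.
#' @export
build_regions <- function(omega, chrom = NULL, threshold = 0.05) {
  g <- rownames(omega)
  m <- length(g)
  adj <- abs(omega) > threshold
  if (!is.null(chrom)) {
    same <- outer(chrom[g], chrom[g], "==")
    adj <- adj & same
  }
  comp <- rep(NA_integer_, m)
  cur <- 0L
  for (i in seq_len(m)) {
    if (!is.na(comp[i])) next
    cur <- cur + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  setNames(comp, g)
}

#' Log Bayes factor of a causal-gene configuration
#'
#' For configuration `c`, with `S = Omega + ridge * I`, compares
#' `z ~ MVN(0, S + v * S[, c] S[c, ])` against `z ~ MVN(0, S)`. Using the
#' matrix determinant lemma and Woodbury identity this reduces to
#' `|c|`-dimensional quantities:
#' `logBF = 1/2 * z_c' ((1/v) I + S_cc)^{-1} z_c
#'          - 1/2 * logdet(I + v * S_cc)`, and `logBF(empty) = 0`.
#'
#' @param config Integer or logical index of genes in the configuration.
#' @param z Gene-level TWAS Z vector.
#' @param omega Gene-gene predicted-expression correlation.
#' @param prior_var Prior effect variance `v`.
#' @param ridge Diagonal regularization added to `omega`.
#' @return Scalar log Bayes factor.
#' @export
config_log_bf <- function(config, z, omega, prior_var = 40, ridge = 0.1) {
  if (is.logical(config)) config <- which(config)
  if (length(config) == 0L) return(0)
  S <- omega + diag(ridge, nrow(omega))
  Scc <- S[config, config, drop = FALSE]
  zc <- z[config]
  k <- length(config)
  M <- diag(1 / prior_var, k) + Scc
  ch <- tryCatch(chol(M), error = function(e)
    abort("singular inner matrix in configuration Bayes factor",
          class = "crosstwas_numeric_error"))
  quad <- drop(crossprod(backsolve(ch, zc, transpose = TRUE)))
  logdet <- determinant(diag(k) + prior_var * Scc, logarithm = TRUE)$modulus
  0.5 * quad - 0.5 * as.numeric(logdet)
}

#' Enumerate causal configurations and compute posterior inclusion
#' probabilities
#'
#' Over all gene subsets of size at most `max_causal` (including the empty,
#' null configuration), the posterior is proportional to
#' `exp(logBF(c)) * p0^|c| * (1 - p0)^(m - |c|)`. The per-gene posterior
#' inclusion probability (PIP) is the posterior mass of configurations
#' containing that gene; the null model is part of the normalization.
#'
#' @param region List with `region_id`, `genes` (ids), `twas_z`, `omega`,
#'   and optionally `prior_prob` (default 1e-3), `prior_var` (default 40),
#'   `max_causal` (default 3), `ridge` (default 0.1).
#' @return A `finemap_result`: list with `pips` tibble (gene, twas_z, pip),
#'   `null_model_posterior`, and the per-configuration log posterior table
#'   `configurations`.
#' @export
enumerate_posterior <- function(region) {
  genes <- region$genes
  m <- length(genes)
  z <- region$twas_z
  omega <- region$omega
  p0 <- region$prior_prob %||% 1e-3
  v <- region$prior_var %||% 40
  max_causal <- min(region$max_causal %||% 3L, m)
  ridge <- region$ridge %||% 0.1
  if (m > 25L && max_causal >= m)
    abort("too many genes to enumerate; set max_causal",
          class = "crosstwas_config_error")
  if (!all(is.finite(z)))
    abort("non-finite TWAS z in region", class = "crosstwas_data_error")

  configs <- list(integer(0))
  for (k in seq_len(max_causal)) {
    configs <- c(configs, combn(m, k, simplify = FALSE))
  }
  logpost <- vapply(configs, function(cf) {
    config_log_bf(cf, z, omega, prior_var = v, ridge = ridge) +
      length(cf) * log(p0) + (m - length(cf)) * log1p(-p0)
  }, numeric(1))
  lse <- max(logpost) + log(sum(exp(logpost - max(logpost))))
  post <- exp(logpost - lse)

  pip <- numeric(m)
  for (i in seq_along(configs)) pip[configs[[i]]] <- pip[configs[[i]]] + post[i]
  pip <- pmin(pip, 1)

  cfg_tbl <- tibble(
    config = vapply(configs, function(cf)
      paste(genes[cf], collapse = "+"), character(1)),
    size = lengths(configs),
    log_posterior = logpost - lse,
    posterior = post)

  structure(list(
    region_id = region$region_id %||% NA_character_,
    pips = tibble(gene = genes, twas_z = z, pip = pip),
    null_model_posterior = post[1],
    configurations = cfg_tbl),
    class = "finemap_result")
}

#' Credible gene set from posterior inclusion probabilities
#'
#' Genes sorted by PIP (descending, ties by gene id) are included until
#' the cumulative normalized PIP reaches `rho`; the gene that crosses the
#' threshold is included, and the `>=` comparison means a gene set whose
#' cumulative share equals `rho` exactly stops there.
#'
#' @param result A `finemap_result` (or tibble with gene, pip).
#' @param rho Credible level.
#' @return Logical vector `in_credible_set` aligned to the result's gene
#'   order.
#' @export
credible_set <- function(result, rho = 0.9) {
  tbl <- if (inherits(result, "finemap_result")) result$pips else result
  total <- sum(tbl$pip)
  if (total <= 0) {
    warn("all PIPs are zero; credible set is empty")
    return(rep(FALSE, nrow(tbl)))
  }
  ord <- order(-tbl$pip, tbl$gene)
  cum <- cumsum(tbl$pip[ord]) / total
  k <- which(cum >= rho)[1]
  if (is.na(k)) k <- length(ord)
  inset <- rep(FALSE, nrow(tbl))
  inset[ord[seq_len(k)]] <- TRUE
  inset
}

#' Fine-map TWAS signals in one tissue
#'
#' Builds the gene-gene predicted-expression correlation from the tissue's
#' models and the reference covariance, splits genes into regions, and
#' enumerates causal configurations per region.
#'
#' @param assoc A `twas_association` tibble restricted to one tissue.
#' @param db A `weight_db` holding that tissue's models.
#' @param ld An `ld_covariance` keyed by gene.
#' @param gene_meta Tibble gene_id, chrom (for region construction).
#' @param genes Optional subset of genes (e.g. the significant set).
#' @param prior_prob,prior_var,max_causal,ridge,rho Fine-mapping
#'   parameters; defaults are the conventional TWAS fine-mapping defaults
#'   (`p0 = 1e-3`, `v = 40`, 90% credible sets).
#' @param region_threshold Absolute correlation joining genes into one
#'   region.
#' @return Tibble (class `twas_finemap`): region, gene, twas_z, pip,
#'   in_credible_set, null_model_posterior; attribute `"results"` holds the
#'   per-region `finemap_result` objects.
#' @export
finemap_tissue <- function(assoc, db, ld, gene_meta, genes = NULL,
                           prior_prob = 1e-3, prior_var = 40,
                           max_causal = 3L, ridge = 0.1, rho = 0.9,
                           region_threshold = 0.05) {
  tissue <- unique(assoc$tissue)
  if (length(tissue) != 1L)
    abort("finemap_tissue expects associations from exactly one tissue",
          class = "crosstwas_data_error")
  if (!is.null(genes)) assoc <- assoc[assoc$gene %in% genes, , drop = FALSE]
  if (nrow(assoc) == 0L)
    return(structure(tibble(region = integer(), gene = character(),
                            twas_z = numeric(), pip = numeric(),
                            in_credible_set = logical(),
                            null_model_posterior = numeric()),
                     class = c("twas_finemap", "tbl_df", "tbl", "data.frame")))

  w_t <- db$weights[db$weights$tissue == tissue &
                      db$weights$gene %in% assoc$gene, , drop = FALSE]
  wl <- lapply(split(w_t, w_t$gene), function(x)
    setNames(x$weight, x$snp_id))
  wl <- wl[intersect(assoc$gene, names(wl))]
  snps <- sort(unique(unlist(lapply(wl, names))))
  # union-frame covariance assembled from the per-gene blocks
  sigma <- union_covariance(ld, names(wl), snps)
  omega <- predicted_expression_correlation(wl, sigma)
  keep <- rownames(omega)
  assoc <- assoc[match(keep, assoc$gene), , drop = FALSE]
  chrom <- setNames(gene_meta$chrom[match(keep, gene_meta$gene_id)], keep)
  regions <- build_regions(omega, chrom = chrom,
                           threshold = region_threshold)

  results <- list()
  rows <- list()
  for (r in sort(unique(regions))) {
    g_r <- names(regions)[regions == r]
    res <- enumerate_posterior(list(
      region_id = as.character(r), genes = g_r,
      twas_z = assoc$z_gene[match(g_r, assoc$gene)],
      omega = omega[g_r, g_r, drop = FALSE],
      prior_prob = prior_prob, prior_var = prior_var,
      max_causal = max_causal, ridge = ridge))
    inset <- credible_set(res, rho = rho)
    results[[as.character(r)]] <- res
    rows[[length(rows) + 1L]] <- dplyr::mutate(
      res$pips, region = r, in_credible_set = inset,
      null_model_posterior = res$null_model_posterior,
      .before = 1)
  }
  out <- dplyr::bind_rows(rows)
  out <- dplyr::select(out, "region", "gene", "twas_z", "pip",
                       "in_credible_set", "null_model_posterior")
  class(out) <- c("twas_finemap", class(out))
  attr(out, "results") <- results
  out
}

# covariance over a union SNP frame, filled from per-gene blocks; SNP
# pairs never seen in one block are taken as uncorrelated (cross-block
# pairs in the simulated designs truly are)
union_covariance <- function(ld, genes, snps) {
  S <- matrix(0, length(snps), length(snps), dimnames = list(snps, snps))
  for (g in genes) {
    blk <- ld[[g]]
    ids <- intersect(rownames(blk), snps)
    S[ids, ids] <- blk[ids, ids]
  }
  S
}

#' @export
print.finemap_result <- function(x, ...) {
  cat(sprintf("<finemap_result> region %s: %d genes, null posterior %.3g\n",
              x$region_id, nrow(x$pips), x$null_model_posterior))
  print(x$pips)
  invisible(x)
}

#' @rdname enumerate_posterior
#' @param x A `finemap_result`.
#' @param ... Unused.
#' @export
tidy.finemap_result <- function(x, ...) x$pips

#' @rdname enumerate_posterior
#' @export
glance.finemap_result <- function(x, ...) {
  tibble(region_id = x$region_id, n_genes = nrow(x$pips),
         null_model_posterior = x$null_model_posterior,
         max_pip = max(x$pips$pip))
}
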