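#' Harmonize model weights with GWAS summary statistics
#'
#' Matches by variant id. When the GWAS effect/other alleles are swapped
#' relative to the model, the GWAS `z` is negated; strand-ambiguous pairs
#' (A/T, C/G), allele mismatches, and ids absent from the GWAS are dropped.
#'
#' @param model Tibble of model SNPs: `snp_id`, `effect_allele`,
#'   `other_allele`, `weight`.
#' @param gwas Tibble: `snp_id`, `effect_allele`, `other_allele`, `z`
#'   (and optionally `n`).
#' @return Tibble of aligned SNPs (`snp_id`, `weight`, `z`, `n` if
#'   present); attribute `"counts"` reports `n_used`, `n_flipped`,
#'   `n_ambiguous`, `n_unmatched`, `n_mismatched`.
#' @export
harmonize_alleles <- function(model, gwas) {
  ambiguous <- function(a, b) (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "C" & b == "G") | (a == "G" & b == "C")

  m <- dplyr::left_join(model, gwas, by = "snp_id",
                        suffix = c("_model", "_gwas"))
  unmatched <- is.na(m$z)
  amb <- !unmatched & ambiguous(m$effect_allele_model, m$other_allele_model)
  same <- !unmatched & !amb &
    m$effect_allele_model == m$effect_allele_gwas &
    m$other_allele_model == m$other_allele_gwas
  swapped <- !unmatched & !amb &
    m$effect_allele_model == m$other_allele_gwas &
    m$other_allele_model == m$effect_allele_gwas
  mismatch <- !unmatched & !amb & !same & !swapped

  m$z[swapped] <- -m$z[swapped]
  keep <- same | swapped
  out <- tibble(snp_id = m$snp_id[keep], weight = m$weight[keep],
                z = m$z[keep])
  if ("n" %in% names(m)) out$n <- m$n[keep]
  attr(out, "counts") <- c(n_used = sum(keep), n_flipped = sum(swapped),
                           n_ambiguous = sum(amb),
                           n_unmatched = sum(unmatched),
                           n_mismatched = sum(mismatch))
  out
}

#' Variance of predicted expression from reference LD
#'
#' `sigma_g^2 = w' Sigma w`, with `Sigma` the reference-panel dosage
#' covariance over the model SNPs. Genes with `sigma_g^2 < 1e-8` are
#' untestable.
#'
#' @param w Weight vector aligned to `sigma`.
#' @param sigma SNP x SNP covariance matrix.
#' @return Scalar `sigma_g^2`.
#' @export
predicted_variance <- function(w, sigma) {
  sigma <- as.matrix(sigma)
  if (length(w) != nrow(sigma) || nrow(sigma) != ncol(sigma))
    abort("weight/covariance dimension mismatch",
          class = "crosstwas_data_error")
  drop(crossprod(w, sigma %*% w))
}

#' Gene-level association Z from summary statistics
#'
#' The summary-statistics TWAS statistic:
#' `Z_g = sum_l w_l (sigma_l / sigma_g) z_l`, where `sigma_l` is the
#' reference SD of SNP `l` and `sigma_g` the SD of predicted expression;
#' `p = 2 * pnorm(-|Z_g|)`.
#'
#' @inheritParams predicted_variance
#' @param z GWAS z-scores aligned to `w`.
#' @return List: `z_gene`, `p`, `sigma_g`.
#' @export
gene_zscore <- function(w, sigma, z) {
  var_g <- predicted_variance(w, sigma)
  if (var_g < 1e-8)
    abort("gene untestable: predicted-expression variance below 1e-8",
          class = "crosstwas_untestable_error")
  sigma_g <- sqrt(var_g)
  zg <- sum(w * sqrt(diag(as.matrix(sigma))) * z) / sigma_g
  list(z_gene = zg, p = 2 * pnorm(-abs(zg)), sigma_g = sigma_g)
}

#' Effect size and confidence interval on the odds-ratio scale
#'
#' Back-converts the gene Z to a log odds ratio per SD of predicted
#' expression using `se_g = 1 / (sigma_g * sqrt(n))`:
#' `effect = Z_g * se_g`, 95% CI `effect +/- 1.96 * se_g`, and the
#' exponentiated OR fields. This per-SD convention is one defensible
#' construction of an OR column from summary output and is flagged as a
#' convention, not an identity.
#'
#' @param z_gene Gene-level Z.
#' @param sigma_g SD of predicted expression.
#' @param n GWAS sample size (NA allowed; effect fields become NA with a
#'   warning).
#' @return List: `effect`, `ci_low`, `ci_high`, `or`, `or_low`, `or_high`.
#' @export
effect_and_ci <- function(z_gene, sigma_g, n) {
  if (is.null(n) || is.na(n) || n <= 0) {
    warn("GWAS sample size missing; effect fields set to NA")
    return(list(effect = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                or = NA_real_, or_low = NA_real_, or_high = NA_real_))
  }
  se <- 1 / (sigma_g * sqrt(n))
  effect <- z_gene * se
  ci <- effect + c(-1, 1) * 1.96 * se
  list(effect = effect, ci_low = ci[1], ci_high = ci[2],
       or = exp(effect), or_low = exp(ci[1]), or_high = exp(ci[2]))
}

#' Reference SNP covariance per gene
#'
#' Dosage covariance over each gene's model (or cis) SNPs, computed from
#' the full reference panel — the same panel for every tissue.
#'
#' @param panel A `reference_panel`.
#' @param snp_sets Named list gene -> character vector of SNP ids.
#' @return Named list of covariance matrices (class `ld_covariance`).
#' @export
snp_covariance <- function(panel, snp_sets) {
  out <- lapply(snp_sets, function(ids) {
    stats::cov(panel$dosages[, ids, drop = FALSE])
  })
  structure(out, class = "ld_covariance")
}

#' Per-gene, per-tissue TWAS associations from summary statistics
#'
#' Applies [harmonize_alleles()], [gene_zscore()] and [effect_and_ci()] to
#' every retained gene-tissue model.
#'
#' @param db A `weight_db` (typically after [retain_models()]).
#' @param gwas A GWAS summary tibble (`snp_id`, `effect_allele`,
#'   `other_allele`, `z`, `n`).
#' @param ld An `ld_covariance` keyed by gene, covering the model SNPs.
#' @return Tibble (class `twas_association`): gene, tissue, z_gene, p,
#'   effect, ci_low, ci_high, or, or_low, or_high, sigma_g, n_snps_used;
#'   attribute `"log"` records skipped models.
#' @export
twas_associate <- function(db, gwas, ld) {
  log_lines <- character(0)
  rows <- list()
  models <- dplyr::group_split(db$weights, .data$gene, .data$tissue)
  for (m in models) {
    gene <- m$gene[1]; tissue <- m$tissue[1]
    h <- harmonize_alleles(m, gwas)
    if (nrow(h) == 0L) {
      log_lines <- c(log_lines, sprintf(
        "model %s/%s skipped: no overlapping SNPs after harmonization",
        gene, tissue))
      next
    }
    sigma <- ld[[gene]][h$snp_id, h$snp_id, drop = FALSE]
    res <- tryCatch(gene_zscore(h$weight, sigma, h$z),
                    crosstwas_untestable_error = function(e) NULL)
    if (is.null(res)) {
      log_lines <- c(log_lines, sprintf(
        "model %s/%s skipped: untestable (sigma_g ~ 0)", gene, tissue))
      next
    }
    n <- if ("n" %in% names(h)) h$n[1] else NA_real_
    eff <- effect_and_ci(res$z_gene, res$sigma_g, n)
    rows[[length(rows) + 1L]] <- tibble(
      gene = gene, tissue = tissue, z_gene = res$z_gene, p = res$p,
      effect = eff$effect, ci_low = eff$ci_low, ci_high = eff$ci_high,
      or = eff$or, or_low = eff$or_low, or_high = eff$or_high,
      sigma_g = res$sigma_g, n_snps_used = nrow(h))
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble(gene = character(), tissue = character(), z_gene = numeric(),
           p = numeric(), effect = numeric(), ci_low = numeric(),
           ci_high = numeric(), or = numeric(), or_low = numeric(),
           or_high = numeric(), sigma_g = numeric(),
           n_snps_used = integer())
  class(out) <- c("twas_association", class(out))
  attr(out, "log") <- log_lines
  out
}
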