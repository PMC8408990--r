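#' Simulation configuration
#'
#' Builds and validates the configuration for the synthetic-data generator.
#' Defaults emulate the reference-panel geometry of a multi-tissue eQTL
#' resource: 838 genotyped donors, ten tissues with the donor counts of the
#' ten brain tissues (205, 147, 165, 129, 194, 202, 170, 114, 170, 237
#' donors), and a GWAS of 455,258 individuals. Scale parameters not fixed by
#' that design (number of genes and SNPs per gene, LD decay, cis
#' heritability, effect sizes) default to desk-scale values typical of the
#' field; see the methods vignette for rationale.
#'
#' @param seed Integer seed; every generator is a pure function of
#'   `(cfg, seed)`.
#' @param n_ref Number of reference-panel individuals (donors).
#' @param n_gwas GWAS sample size (used for effect-size back-conversion).
#' @param n_snps_per_gene SNPs in each gene's cis block.
#' @param n_genes Number of genes.
#' @param n_tissues Number of tissues.
#' @param maf_range Length-2 numeric in (0, 0.5]; minor allele frequencies
#'   are drawn uniformly on this interval.
#' @param ld_rho AR(1) adjacent-SNP correlation of the latent Gaussian
#'   copula, in \[0, 1).
#' @param n_causal_eqtl Causal eQTLs per gene.
#' @param h2_expr Cis heritability of expression in \[0, 1\]; noise variance
#'   is exactly `1 - h2_expr`.
#' @param cross_tissue_cor Correlation of a causal SNP's effect across
#'   tissues, in \[0, 1\].
#' @param causal_gene_frac Fraction of genes with a nonzero effect on the
#'   trait.
#' @param gene_effect_sd Standard deviation of the per-gene trait effect
#'   (log-odds per unit of genetic expression score).
#' @param tissue_sample_fracs Per-tissue fraction of panel donors with
#'   expression, each in (0, 1\]. Recycled/truncated to `n_tissues`.
#' @param shared_blocks If `TRUE`, consecutive gene pairs share one SNP
#'   block (overlapping cis windows) to exercise fine-mapping; causal eQTL
#'   sets of the two genes are kept disjoint.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_ref = 838L,
                       n_gwas = 455258L,
                       n_snps_per_gene = 30L,
                       n_genes = 50L,
                       n_tissues = 10L,
                       maf_range = c(0.05, 0.5),
                       ld_rho = 0.5,
                       n_causal_eqtl = 3L,
                       h2_expr = 0.2,
                       cross_tissue_cor = 0.8,
                       causal_gene_frac = 0.1,
                       gene_effect_sd = 0.02,
                       tissue_sample_fracs = c(205, 147, 165, 129, 194,
                                               202, 170, 114, 170, 237) / 838,
                       shared_blocks = FALSE) {
  cfg <- list(
    seed = as.integer(seed), n_ref = as.integer(n_ref),
    n_gwas = as.integer(n_gwas),
    n_snps_per_gene = as.integer(n_snps_per_gene),
    n_genes = as.integer(n_genes), n_tissues = as.integer(n_tissues),
    maf_range = as.numeric(maf_range), ld_rho = as.numeric(ld_rho),
    n_causal_eqtl = as.integer(n_causal_eqtl),
    h2_expr = as.numeric(h2_expr),
    cross_tissue_cor = as.numeric(cross_tissue_cor),
    causal_gene_frac = as.numeric(causal_gene_frac),
    gene_effect_sd = as.numeric(gene_effect_sd),
    tissue_sample_fracs = rep_len(as.numeric(tissue_sample_fracs),
                                  as.integer(n_tissues)),
    shared_blocks = isTRUE(shared_blocks)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stop_cfg <- function(field, msg) {
    abort(sprintf("invalid simulation config: field `%s` %s", field, msg),
          class = "crosstwas_config_error")
  }
  counts <- c("n_ref", "n_gwas", "n_snps_per_gene", "n_genes", "n_tissues",
              "n_causal_eqtl")
  for (f in counts) {
    v <- cfg[[f]]
    if (length(v) != 1L || is.na(v) || v < 1L) stop_cfg(f, "must be a count >= 1")
  }
  if (length(cfg$maf_range) != 2L || any(is.na(cfg$maf_range)) ||
      cfg$maf_range[1] <= 0 || cfg$maf_range[2] > 0.5 ||
      cfg$maf_range[1] > cfg$maf_range[2])
    stop_cfg("maf_range", "must be an increasing pair within (0, 0.5]")
  if (is.na(cfg$ld_rho) || cfg$ld_rho < 0 || cfg$ld_rho >= 1)
    stop_cfg("ld_rho", "must lie in [0, 1)")
  if (is.na(cfg$h2_expr) || cfg$h2_expr < 0 || cfg$h2_expr > 1)
    stop_cfg("h2_expr", "must lie in [0, 1]")
  if (is.na(cfg$cross_tissue_cor) || cfg$cross_tissue_cor < 0 ||
      cfg$cross_tissue_cor > 1)
    stop_cfg("cross_tissue_cor", "must lie in [0, 1]")
  if (is.na(cfg$causal_gene_frac) || cfg$causal_gene_frac < 0 ||
      cfg$causal_gene_frac > 1)
    stop_cfg("causal_gene_frac", "must lie in [0, 1]")
  if (is.na(cfg$gene_effect_sd) || cfg$gene_effect_sd < 0)
    stop_cfg("gene_effect_sd", "must be >= 0")
  if (any(is.na(cfg$tissue_sample_fracs)) ||
      any(cfg$tissue_sample_fracs <= 0) || any(cfg$tissue_sample_fracs > 1))
    stop_cfg("tissue_sample_fracs", "must each lie in (0, 1]")
  if (cfg$n_causal_eqtl > cfg$n_snps_per_gene)
    stop_cfg("n_causal_eqtl", "must not exceed n_snps_per_gene")
  if (cfg$shared_blocks && cfg$n_snps_per_gene < 2L * cfg$n_causal_eqtl)
    stop_cfg("n_causal_eqtl",
             "shared blocks need n_snps_per_gene >= 2 * n_causal_eqtl")
  invisible(cfg)
}
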