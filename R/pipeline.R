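#' Pipeline run configuration
#'
#' Collects every stage's parameters into a single validated, serializable
#' object. Unknown keys are rejected.
#'
#' @param seed Integer master seed for the run.
#' @param stages Character subset of
#'   `c("simulate", "train", "associate", "combine", "finemap")`, executed
#'   in that order.
#' @param sim Named list of [sim_config()] overrides (the `seed` is taken
#'   from the run seed).
#' @param window cis window in bp.
#' @param n_folds Cross-validation folds.
#' @param n_lambda Ladder length per hyperparameter of the default grid.
#' @param alpha Family-wise error rate for Bonferroni selection.
#' @param rho Credible-set level.
#' @param prior_prob,prior_var,max_causal,ridge Fine-mapping parameters.
#' @param region_threshold Absolute correlation joining genes into one
#'   fine-mapping region.
#' @param blacklist Region blacklist tibble (default: extended MHC).
#' @param out_dir Output directory; `NULL` disables file output.
#' @param ... Unknown keys: an error.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       stages = c("simulate", "train", "associate",
                                  "combine", "finemap"),
                       sim = list(),
                       window = 1e6, n_folds = 5L, n_lambda = 10L,
                       alpha = 0.05, rho = 0.9, prior_prob = 1e-3,
                       prior_var = 40, max_causal = 3L, ridge = 0.1,
                       region_threshold = 0.05,
                       blacklist = default_region_blacklist(),
                       out_dir = NULL, ...) {
  extra <- list(...)
  if (length(extra))
    abort(sprintf("unknown run_config keys: %s",
                  paste(names(extra), collapse = ", ")),
          class = "crosstwas_config_error")
  bad <- setdiff(stages, c("simulate", "train", "associate", "combine",
                           "finemap"))
  if (length(bad))
    abort(sprintf("unknown stages: %s", paste(bad, collapse = ", ")),
          class = "crosstwas_config_error")
  if (!is.list(sim) || (length(sim) && is.null(names(sim))))
    abort("`sim` must be a named list of sim_config overrides",
          class = "crosstwas_config_error")
  structure(list(seed = as.integer(seed), stages = stages, sim = sim,
                 window = window, n_folds = as.integer(n_folds),
                 n_lambda = as.integer(n_lambda), alpha = alpha, rho = rho,
                 prior_prob = prior_prob, prior_var = prior_var,
                 max_causal = as.integer(max_causal), ridge = ridge,
                 region_threshold = region_threshold,
                 blacklist = blacklist, out_dir = out_dir),
            class = "run_config")
}

#' Run the TWAS pipeline end to end
#'
#' Executes the enabled stages in order: simulate (genotypes, expression,
#' GWAS), train (cross-tissue models + retention), associate
#' (summary-statistics gene Z per tissue), combine (Cauchy combination +
#' Bonferroni + region exclusion), finemap (per-tissue credible sets over
#' the significant genes). With a fixed `cfg` the run is fully
#' deterministic: manifests from identical configs have identical
#' checksums.
#'
#' @param cfg A [run_config()].
#' @param data Optional pre-existing input list (`panel`, `tissues`,
#'   `truth`, `gwas`) for runs that skip the simulate stage.
#' @return A `run_manifest`: list with `config`, `version`, `counts`,
#'   `checksums`, `threshold`, and the stage outputs (`data`, `db`,
#'   `associations`, `combined`, `finemap`).
#' @export
run_pipeline <- function(cfg, data = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  out_dir <- cfg$out_dir
  if (!is.null(out_dir))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  emit <- function(x, name, kind) {
    if (is.null(out_dir)) return(invisible(NULL))
    path <- file.path(out_dir, name)
    write_twas_file(x, path, kind)
    files <<- c(files, path)
  }
  counts <- list()

  if ("simulate" %in% cfg$stages) {
    scfg <- do.call(sim_config, c(list(seed = cfg$seed), cfg$sim))
    data <- simulate_twas_data(scfg)
    emit(data$panel$dosages, "panel_dosages.tsv", "panel")
    emit(data$panel$snp_meta, "panel_snps.tsv", "snp_meta")
    emit(data$panel$gene_meta, "panel_genes.tsv", "gene_meta")
    if (!is.null(out_dir)) {
      for (ts in data$tissues)
        emit(ts$expression, sprintf("expression_%s.tsv", ts$tissue),
             "expression")
      write_gwas_sumstats(data$gwas, file.path(out_dir, "gwas_sumstats.tsv"))
      files <- c(files, file.path(out_dir, "gwas_sumstats.tsv"))
      write_truth_json(data$truth, file.path(out_dir, "truth.json"))
      files <- c(files, file.path(out_dir, "truth.json"))
    }
  }
  if (is.null(data) && length(setdiff(cfg$stages, "simulate")))
    abort("no input data: run the simulate stage first (or pass `data`)",
          class = "crosstwas_config_error")

  db <- NULL; assoc <- NULL; combined <- NULL; fm <- NULL; ld <- NULL
  threshold <- NA_real_

  if ("train" %in% cfg$stages) {
    db_all <- train_expression_models(
      data$panel, data$tissues, window = cfg$window, n_folds = cfg$n_folds,
      seed = cfg$seed, n_lambda = cfg$n_lambda)
    db <- retain_models(db_all)
    counts$models_trained <- nrow(db_all$extra)
    counts$models_retained <- nrow(db$extra)
    counts$genes_tested <- dplyr::n_distinct(db$extra$gene)
    if (!is.null(out_dir)) {
      write_weight_db(db, out_dir)
      files <- c(files, file.path(out_dir, c("weights.tsv", "extra.tsv")))
    }
  }

  if ("associate" %in% cfg$stages) {
    if (is.null(db))
      abort("association needs trained models: run the train stage first",
            class = "crosstwas_config_error")
    gm <- data$panel$gene_meta
    cis_sets <- setNames(lapply(seq_len(nrow(gm)), function(i)
      select_cis_snps(data$panel$snp_meta, gm$tss[i], gm$tes[i],
                      chrom = gm$chrom[i], window = cfg$window)),
      gm$gene_id)
    cis_sets <- cis_sets[unique(db$weights$gene)]
    ld <- snp_covariance(data$panel, cis_sets)
    assoc <- twas_associate(db, data$gwas, ld)
    counts$associations <- nrow(assoc)
    emit(assoc, "associations.tsv", "associations")
    if (!is.null(out_dir)) {
      write_twas_file(cov_to_long(ld), file.path(out_dir, "covariance.tsv"),
                      "covariance")
      files <- c(files, file.path(out_dir, "covariance.tsv"))
    }
  }

  if ("combine" %in% cfg$stages) {
    if (is.null(assoc))
      abort("combination needs associations: run the associate stage first",
            class = "crosstwas_config_error")
    combined <- combine_tissues(assoc)
    combined <- select_significant(combined, data$panel$gene_meta,
                                   alpha = cfg$alpha,
                                   blacklist = cfg$blacklist)
    threshold <- attr(combined, "threshold")
    counts$genes_combined <- nrow(combined)
    counts$genes_significant <- sum(combined$significant)
    counts$genes_excluded_region <- sum(combined$excluded_region)
    flat <- dplyr::mutate(combined, tissue_ps = purrr::map_chr(
      .data$tissue_ps, function(p)
        as.character(jsonlite::toJSON(p, digits = NA))))
    emit(flat, "combined.tsv", "combined")
  }

  if ("finemap" %in% cfg$stages) {
    if (is.null(combined))
      abort("fine-mapping needs combined results: run the combine stage first",
            class = "crosstwas_config_error")
    sig_genes <- combined$gene[combined$significant]
    fm_list <- list()
    for (ts in unique(assoc$tissue)) {
      a_t <- assoc[assoc$tissue == ts, , drop = FALSE]
      g_t <- intersect(sig_genes, a_t$gene)
      if (length(g_t) == 0L) next
      res <- finemap_tissue(a_t, db, ld, data$panel$gene_meta, genes = g_t,
                            prior_prob = cfg$prior_prob,
                            prior_var = cfg$prior_var,
                            max_causal = cfg$max_causal, ridge = cfg$ridge,
                            rho = cfg$rho,
                            region_threshold = cfg$region_threshold)
      if (nrow(res)) fm_list[[ts]] <- dplyr::mutate(res, tissue = ts,
                                                    .before = 1)
    }
    fm <- if (length(fm_list)) dplyr::bind_rows(fm_list) else
      tibble(tissue = character(), region = integer(), gene = character(),
             twas_z = numeric(), pip = numeric(),
             in_credible_set = logical(), null_model_posterior = numeric())
    counts$genes_in_credible_sets <-
      dplyr::n_distinct(fm$gene[fm$in_credible_set])
    if (!is.null(out_dir)) {
      readr::write_tsv(fm, file.path(out_dir, "finemap.tsv"),
                       progress = FALSE)
      files <- c(files, file.path(out_dir, "finemap.tsv"))
    }
  }

  checksums <- if (length(files)) tools::md5sum(sort(unique(files))) else
    character(0)
  structure(list(config = cfg,
                 version = as.character(utils::packageVersion("crosstwas")),
                 counts = counts, checksums = checksums,
                 threshold = threshold,
                 data = data, db = db, associations = assoc,
                 combined = combined, finemap = fm),
            class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest>\n")
  for (nm in names(x$counts)) cat(sprintf("  %s: %s\n", nm, x$counts[[nm]]))
  if (is.finite(x$threshold))
    cat(sprintf("  bonferroni threshold: %.3g\n", x$threshold))
  invisible(x)
}

#' @rdname run_pipeline
#' @param x A `run_manifest`.
#' @param ... Unused.
#' @export
glance.run_manifest <- function(x, ...) {
  as_tibble(c(list(version = x$version, seed = x$config$seed,
                   threshold = x$threshold), x$counts))
}
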