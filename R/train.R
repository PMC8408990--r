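#' Select cis SNPs for a gene
#'
#' SNPs whose position lies in the closed interval
#' `[tss - window, tes + window]` (1-based coordinates) on the gene's
#' chromosome. The default window of 1 Mb up- and downstream mirrors the
#' usual cis definition for expression prediction models.
#'
#' @param snp_meta Tibble with `snp_id`, `chrom`, `pos`.
#' @param tss,tes Transcription start/end (1-based).
#' @param chrom Chromosome; when `NULL` all rows are considered.
#' @param window Flank size in bp.
#' @return Character vector of SNP ids (possibly empty).
#' @export
select_cis_snps <- function(snp_meta, tss, tes, chrom = NULL,
                            window = 1e6) {
  keep <- snp_meta$pos >= (tss - window) & snp_meta$pos <= (tes + window)
  if (!is.null(chrom)) keep <- keep & snp_meta$chrom == chrom
  snp_meta$snp_id[keep]
}

# per-tissue fold labels, stratified within tissue, seeded
make_cv_folds <- function(n_per_tissue, n_folds, seed) {
  set.seed(seed)
  lapply(n_per_tissue, function(n)
    sample(rep(seq_len(n_folds), length.out = n)))
}

# standardize columns with training-set statistics; near-constant columns
# are zeroed so they carry no weight
std_with <- function(X, center, scale) {
  bad <- scale < 1e-12
  scale[bad] <- 1
  Xs <- sweep(sweep(X, 2, center, "-"), 2, scale, "/")
  if (any(bad)) Xs[, bad] <- 0
  Xs
}

#' Consistent-grid cross-validated hyperparameter tuning
#'
#' For every `(lambda1, lambda2)` pair in the grid (the same ordered list in
#' every fold) and every fold: fit on the other folds, record validation
#' mean squared error per tissue, then average over tissues and over folds.
#' The pair with the lowest average tuning error is selected; ties go to
#' the larger `lambda1` (then larger `lambda2`), i.e. the sparser model,
#' and exact duplicates to the first occurrence. Out-of-fold predictions
#' under the selected pair are concatenated across folds. Standardization
#' statistics are computed on each training fold only and applied to its
#' validation fold, so no information leaks.
#'
#' @param X,Y Lists per tissue: dosage matrices (tissue samples x cis SNPs)
#'   and centred expression vectors.
#' @param grid Tibble of `lambda1`, `lambda2` pairs (see
#'   [make_lambda_grid()]).
#' @param n_folds Number of folds.
#' @param seed Seed for the fold assignment.
#' @param tol,max_iter Passed to [fit_sparse_group_lasso()].
#' @return List: `lambda1`, `lambda2` (selected pair), `cv_errors`
#'   (tibble pair x error), `oof` (per-tissue out-of-fold predictions on
#'   the observed scale), `folds` (per-tissue fold labels).
#' @export
tune_consistent_grid <- function(X, Y, grid, n_folds = 5L, seed = 1L,
                                 tol = 1e-6, max_iter = 5000L) {
  stopifnot(nrow(grid) >= 1L, length(X) == length(Y))
  d <- length(X)
  p <- ncol(X[[1]])
  folds <- make_cv_folds(vapply(Y, length, integer(1)), n_folds, seed)

  # per-fold training statistics and Gram forms, computed once
  fold_data <- lapply(seq_len(n_folds), function(k) {
    Xtr <- vector("list", d); Ytr <- vector("list", d)
    Xva <- vector("list", d); Yva <- vector("list", d)
    ctr <- vector("list", d); sca <- vector("list", d); my <- numeric(d)
    ok <- logical(d)
    for (t in seq_len(d)) {
      tr <- folds[[t]] != k
      va <- !tr
      if (sum(va) < 2L || sum(tr) < 2L) {
        inform(sprintf(
          "tissue %d excluded from fold %d error (<2 validation samples)",
          t, k))
        ok[t] <- FALSE
        next
      }
      ok[t] <- TRUE
      ctr[[t]] <- colMeans(X[[t]][tr, , drop = FALSE])
      sca[[t]] <- apply(X[[t]][tr, , drop = FALSE], 2, stats::sd)
      my[t] <- mean(Y[[t]][tr])
      Xtr[[t]] <- std_with(X[[t]][tr, , drop = FALSE], ctr[[t]], sca[[t]])
      Ytr[[t]] <- Y[[t]][tr] - my[t]
      Xva[[t]] <- std_with(X[[t]][va, , drop = FALSE], ctr[[t]], sca[[t]])
      Yva[[t]] <- Y[[t]][va]
    }
    gram <- sgl_gram(Xtr[ok], Ytr[ok])
    list(ok = ok, gram = gram, Xva = Xva, Yva = Yva, my = my)
  })

  n_pairs <- nrow(grid)
  err <- matrix(NA_real_, n_pairs, n_folds)
  warm <- vector("list", n_folds)
  # exact duplicate pairs reuse the first occurrence's error, so the
  # documented first-occurrence tie rule is reachable
  pair_key <- paste(grid$lambda1, grid$lambda2)
  first_of <- match(pair_key, pair_key)
  for (i in seq_len(n_pairs)) {
    if (first_of[i] < i) {
      err[i, ] <- err[first_of[i], ]
      next
    }
    for (k in seq_len(n_folds)) {
      fd <- fold_data[[k]]
      fit <- fit_sparse_group_lasso(NULL, NULL, grid$lambda1[i],
                                    grid$lambda2[i], tol = tol,
                                    max_iter = max_iter,
                                    init = warm[[k]], gram = fd$gram)
      warm[[k]] <- fit$weights
      tset <- which(fd$ok)
      mse <- vapply(seq_along(tset), function(ti) {
        t <- tset[ti]
        pred <- drop(fd$Xva[[t]] %*% fit$weights[, ti]) + fd$my[t]
        mean((fd$Yva[[t]] - pred)^2)
      }, numeric(1))
      err[i, k] <- mean(mse)
    }
  }
  avg <- rowMeans(err)
  cand <- which(avg == min(avg))
  if (length(cand) > 1L) {
    o <- order(-grid$lambda1[cand], -grid$lambda2[cand], cand)
    cand <- cand[o]
  }
  sel <- cand[1L]

  # out-of-fold predictions under the selected pair
  oof <- lapply(Y, function(y) rep(NA_real_, length(y)))
  for (k in seq_len(n_folds)) {
    fd <- fold_data[[k]]
    fit <- fit_sparse_group_lasso(NULL, NULL, grid$lambda1[sel],
                                  grid$lambda2[sel], tol = tol,
                                  max_iter = max_iter, gram = fd$gram)
    tset <- which(fd$ok)
    for (ti in seq_along(tset)) {
      t <- tset[ti]
      va <- folds[[t]] == k
      oof[[t]][va] <- drop(fd$Xva[[t]] %*% fit$weights[, ti]) + fd$my[t]
    }
  }

  list(lambda1 = grid$lambda1[sel], lambda2 = grid$lambda2[sel],
       selected = sel,
       cv_errors = dplyr::mutate(grid, error = avg),
       oof = oof, folds = folds)
}

#' Out-of-fold prediction performance
#'
#' Pearson correlation between pooled out-of-fold predictions and observed
#' expression, with a two-sided P value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom. A
#' constant prediction vector is defined to have `r = 0`, `p = 1`.
#'
#' @param predicted,observed Aligned numeric vectors (NA pairs dropped).
#' @return One-row tibble: `r`, `p`, `n_eval`, `r2` (`r^2` when `r > 0`,
#'   else 0).
#' @export
evaluate_performance <- function(predicted, observed) {
  if (length(predicted) != length(observed))
    abort("predicted and observed lengths differ",
          class = "crosstwas_data_error")
  keep <- is.finite(predicted) & is.finite(observed)
  predicted <- predicted[keep]; observed <- observed[keep]
  n <- length(predicted)
  if (n < 3L)
    abort("need at least 3 evaluation pairs", class = "crosstwas_data_error")
  if (stats::sd(predicted) < 1e-12 || stats::sd(observed) < 1e-12) {
    r <- 0; p <- 1
  } else {
    r <- stats::cor(predicted, observed)
    if (abs(r) >= 1) {
      p <- 0
    } else {
      tstat <- r * sqrt((n - 2) / (1 - r^2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
  }
  tibble(r = r, p = p, n_eval = n, r2 = if (r > 0) r^2 else 0)
}

#' Retain prediction models that meet the performance rule
#'
#' Keeps gene-tissue models with Pearson `r >= 0.1` and `p < 0.05` (both
#' boundaries as written: `r = 0.1` is kept when `p < 0.05`; `p = 0.05` is
#' dropped). The `r >= 0.1` floor corresponds to a retained-model `r^2` of
#' at least 0.01.
#'
#' @param db A `weight_db` (see [train_expression_models()]).
#' @return A filtered `weight_db`; attribute `"tissue_counts"` tabulates
#'   retained models and models with `r2 >= 0.01` per tissue.
#' @export
retain_models <- function(db) {
  keep <- db$extra$r >= 0.1 & db$extra$p < 0.05
  extra <- db$extra[keep, , drop = FALSE]
  weights <- dplyr::semi_join(db$weights, extra, by = c("gene", "tissue"))
  counts <- extra |>
    dplyr::group_by(.data$tissue) |>
    dplyr::summarise(n_retained = dplyr::n(),
                     n_r2_ge_0.01 = sum(.data$r2 >= 0.01), .groups = "drop")
  out <- structure(list(weights = weights, extra = extra),
                   class = "weight_db")
  attr(out, "tissue_counts") <- counts
  out
}

#' Train cross-tissue expression prediction models for all genes
#'
#' Per gene: select cis SNPs, tune `(lambda1, lambda2)` on a consistent
#' grid by five-fold cross-validation, evaluate each tissue's performance
#' from the pooled out-of-fold predictions, then refit on the full data at
#' the selected pair for the final weights (performance is still reported
#' from the out-of-fold predictions only). Weights are stored on the
#' effect-allele dosage scale; only nonzero weights are kept.
#'
#' @param panel A `reference_panel`.
#' @param tissues List of `tissue_expression` (see
#'   [simulate_expression()]), or any list with `tissue`, `samples`,
#'   `expression`.
#' @param window cis window in bp.
#' @param grid Optional `(lambda1, lambda2)` tibble; default is the
#'   [make_lambda_grid()] 10 x 10 geometric grid computed per gene.
#' @param n_folds,seed,tol,max_iter Tuning controls.
#' @param n_lambda Ladder length per hyperparameter for the default grid.
#' @param genes Optional subset of gene ids.
#' @return A `weight_db`: list with `weights` (tibble: gene, tissue,
#'   snp_id, chrom, pos, effect_allele, other_allele, weight) and `extra`
#'   (tibble: gene, tissue, n_snps, r, p, n_eval, r2, lambda1, lambda2);
#'   attribute `"log"` records skipped genes.
#' @export
train_expression_models <- function(panel, tissues, window = 1e6,
                                    grid = NULL, n_folds = 5L, seed = 1L,
                                    tol = 1e-6, max_iter = 5000L,
                                    n_lambda = 10L, genes = NULL) {
  gm <- panel$gene_meta
  if (!is.null(genes)) gm <- gm[gm$gene_id %in% genes, , drop = FALSE]
  log_lines <- character(0)
  w_list <- list(); e_list <- list()

  for (gi in seq_len(nrow(gm))) {
    gene <- gm$gene_id[gi]
    cis <- select_cis_snps(panel$snp_meta, gm$tss[gi], gm$tes[gi],
                           chrom = gm$chrom[gi], window = window)
    if (length(cis) == 0L) {
      log_lines <- c(log_lines, sprintf("gene %s skipped: no cis SNPs", gene))
      next
    }
    meta_cis <- panel$snp_meta[match(cis, panel$snp_meta$snp_id), ]
    X <- lapply(tissues, function(ts)
      panel$dosages[ts$samples, cis, drop = FALSE])
    Y <- lapply(tissues, function(ts) {
      y <- ts$expression[, gene]
      y - mean(y)
    })

    # grid on fully standardized data so lambda_max is exact
    ctr <- lapply(X, colMeans)
    sca <- lapply(X, function(x) apply(x, 2, stats::sd))
    Xs <- lapply(seq_along(X), function(t) std_with(X[[t]], ctr[[t]], sca[[t]]))
    g <- grid %||% make_lambda_grid(Xs, Y, n_lambda, n_lambda)

    tuned <- tune_consistent_grid(X, Y, g, n_folds = n_folds,
                                  seed = seed + gi, tol = tol,
                                  max_iter = max_iter)
    fit <- fit_sparse_group_lasso(Xs, Y, tuned$lambda1, tuned$lambda2,
                                  tol = tol, max_iter = max_iter)

    for (t in seq_along(tissues)) {
      perf <- evaluate_performance(tuned$oof[[t]], Y[[t]])
      e_list[[length(e_list) + 1L]] <- dplyr::mutate(
        perf, gene = gene, tissue = tissues[[t]]$tissue,
        n_snps = sum(fit$weights[, t] != 0),
        lambda1 = tuned$lambda1, lambda2 = tuned$lambda2,
        .before = 1)
      nz <- which(fit$weights[, t] != 0)
      if (length(nz) > 0L) {
        scale_t <- sca[[t]][nz]
        scale_t[scale_t < 1e-12] <- Inf        # zeroed constant columns
        w_list[[length(w_list) + 1L]] <- tibble(
          gene = gene, tissue = tissues[[t]]$tissue,
          snp_id = meta_cis$snp_id[nz], chrom = meta_cis$chrom[nz],
          pos = meta_cis$pos[nz],
          effect_allele = meta_cis$effect_allele[nz],
          other_allele = meta_cis$other_allele[nz],
          weight = fit$weights[nz, t] / scale_t)
      }
    }
  }

  weights <- if (length(w_list)) dplyr::bind_rows(w_list) else
    tibble(gene = character(), tissue = character(), snp_id = character(),
           chrom = character(), pos = numeric(), effect_allele = character(),
           other_allele = character(), weight = numeric())
  extra <- if (length(e_list)) {
    dplyr::bind_rows(e_list) |>
      dplyr::select("gene", "tissue", "n_snps", "r", "p", "n_eval", "r2",
                    "lambda1", "lambda2")
  } else {
    tibble(gene = character(), tissue = character(), n_snps = integer(),
           r = numeric(), p = numeric(), n_eval = integer(), r2 = numeric(),
           lambda1 = numeric(), lambda2 = numeric())
  }
  structure(list(weights = weights, extra = extra),
            class = "weight_db", log = log_lines)
}

#' In-sample performance of a full-data refit
#'
#' Fits the sparse-group LASSO on the complete data at a fixed pair and
#' evaluates the Pearson correlation on the same samples. This is the
#' evaluation protocol whose optimism the out-of-fold protocol removes;
#' exposed so the two can be contrasted directly.
#'
#' @inheritParams tune_consistent_grid
#' @param lambda1,lambda2 Penalty pair.
#' @return Tibble, one row per tissue: `tissue`, `r`, `p`, `n_eval`, `r2`.
#' @export
insample_performance <- function(X, Y, lambda1, lambda2, tol = 1e-6,
                                 max_iter = 5000L) {
  ctr <- lapply(X, colMeans)
  sca <- lapply(X, function(x) apply(x, 2, stats::sd))
  Xs <- lapply(seq_along(X), function(t) std_with(X[[t]], ctr[[t]], sca[[t]]))
  Yc <- lapply(Y, function(y) y - mean(y))
  fit <- fit_sparse_group_lasso(Xs, Yc, lambda1, lambda2, tol = tol,
                                max_iter = max_iter)
  purrr::map_dfr(seq_along(X), function(t) {
    pred <- drop(Xs[[t]] %*% fit$weights[, t])
    dplyr::mutate(evaluate_performance(pred, Yc[[t]]), tissue = t,
                  .before = 1)
  })
}

#' @export
print.weight_db <- function(x, ...) {
  cat(sprintf("<weight_db> %d gene-tissue models, %d weight rows\n",
              nrow(x$extra), nrow(x$weights)))
  invisible(x)
}

#' @rdname train_expression_models
#' @param x A `weight_db`.
#' @param ... Unused.
#' @export
tidy.weight_db <- function(x, ...) x$weights

#' @rdname train_expression_models
#' @export
glance.weight_db <- function(x, ...) {
  tibble(n_models = nrow(x$extra),
         n_genes = dplyr::n_distinct(x$extra$gene),
         n_tissues = dplyr::n_distinct(x$extra$tissue),
         median_r = stats::median(x$extra$r),
         n_r2_ge_0.01 = sum(x$extra$r2 >= 0.01))
}
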