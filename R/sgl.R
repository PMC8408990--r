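#' Sparse-group-LASSO objective for cross-tissue weights
#'
#' `sum_t (1/(2 N_t)) ||y_t - X_t b_t||^2 + lambda1 * sum |b| +
#' lambda2 * sum_j ||B[j, ]||_2`. The `1/(2 N_t)` loss normalization
#' equalizes tissue contributions across unequal sample sizes and makes the
#' lambda scales comparable across tissues.
#'
#' @param B SNPs x tissues weight matrix.
#' @param X,Y Lists (one element per tissue) of design matrices and
#'   responses.
#' @param lambda1,lambda2 Within-tissue L1 and cross-tissue group-L2
#'   penalties.
#' @return Objective value (scalar).
#' @export
sgl_objective <- function(B, X, Y, lambda1, lambda2) {
  loss <- sum(vapply(seq_along(X), function(t) {
    r <- Y[[t]] - X[[t]] %*% B[, t]
    sum(r^2) / (2 * length(Y[[t]]))
  }, numeric(1)))
  loss + lambda1 * sum(abs(B)) +
    lambda2 * sum(sqrt(rowSums(B^2)))
}

# sparse-group proximal map: coordinate soft-threshold by t1,
# then row-wise group shrinkage by t2
sgl_prox <- function(B, t1, t2) {
  B <- sign(B) * pmax(abs(B) - t1, 0)
  if (t2 > 0) {
    rn <- sqrt(rowSums(B^2))
    shrink <- ifelse(rn > 0, pmax(1 - t2 / rn, 0), 0)
    B <- B * shrink
  }
  B
}

#' Smallest L1 penalty that zeroes every weight
#'
#' `lambda_max = max_{j,t} |X_t' y_t| / N_t`; with `lambda2 = 0` and
#' `lambda1 >= lambda_max` the all-zero matrix solves the problem.
#'
#' @inheritParams sgl_objective
#' @return Scalar.
#' @export
sgl_lambda_max <- function(X, Y) {
  max(vapply(seq_along(X), function(t)
    max(abs(crossprod(X[[t]], Y[[t]])) / length(Y[[t]])), numeric(1)))
}

#' Geometric hyperparameter ladder crossed into a pair grid
#'
#' Ten values per hyperparameter (by default) from `lambda_max` down to
#' `min_frac * lambda_max`, geometrically spaced, crossed into pairs. The
#' same ordered list is used in every cross-validation fold.
#'
#' @inheritParams sgl_objective
#' @param n_lambda1,n_lambda2 Ladder lengths.
#' @param min_frac Smallest value as a fraction of `lambda_max`.
#' @return Tibble with columns `lambda1`, `lambda2`, ordered large-to-small.
#' @export
make_lambda_grid <- function(X, Y, n_lambda1 = 10, n_lambda2 = 10,
                             min_frac = 1e-3) {
  lmax <- sgl_lambda_max(X, Y)
  ladder <- function(k) exp(seq(log(lmax), log(min_frac * lmax),
                                length.out = k))
  tidyr::expand_grid(lambda1 = ladder(n_lambda1),
                     lambda2 = ladder(n_lambda2))
}

#' Fit the cross-tissue sparse-group LASSO by proximal gradient
#'
#' Minimizes [sgl_objective()] by ISTA with the sparse-group proximal map
#' (soft-threshold then row-wise group shrinkage). The step size is
#' `1 / max_t eigmax(X_t'X_t / N_t)`, which makes the recorded objective
#' trace non-increasing. Iteration stops when the relative objective change
#' drops below `tol` or at `max_iter` (the latter sets a `converged = FALSE`
#' flag rather than erroring).
#'
#' @inheritParams sgl_objective
#' @param tol Relative objective-change tolerance.
#' @param max_iter Iteration cap.
#' @param init Optional warm-start weight matrix.
#' @param gram Optional precomputed list with elements `G` (list of
#'   `X_t'X_t / N_t`), `c` (list of `X_t'y_t / N_t`), `L` (step Lipschitz
#'   constant), `yss` (list of `sum(y_t^2) / (2 N_t)`); see
#'   [sgl_gram()]. When supplied, `X`/`Y` may be `NULL`.
#' @return An object of class `sgl_fit`: `weights` (SNPs x tissues),
#'   `objective_trace`, `converged`, `n_iter`, `lambda1`, `lambda2`.
#' @export
fit_sparse_group_lasso <- function(X, Y, lambda1, lambda2, tol = 1e-6,
                                   max_iter = 5000L, init = NULL,
                                   gram = NULL) {
  if (is.null(gram)) {
    for (t in seq_along(X)) {
      if (!all(is.finite(X[[t]])) || !all(is.finite(Y[[t]])))
        abort("non-finite values in training data",
              class = "crosstwas_data_error")
    }
    gram <- sgl_gram(X, Y)
  }
  p <- nrow(gram$G[[1]])
  d <- length(gram$G)
  B <- if (is.null(init)) matrix(0, p, d) else init
  s <- 1 / gram$L

  obj_quad <- function(B) {
    # quadratic loss via Gram form: sum_t (B'GB/2 - c'B + yss)
    sum(vapply(seq_len(d), function(t) {
      b <- B[, t]
      drop(crossprod(b, gram$G[[t]] %*% b)) / 2 -
        drop(crossprod(gram$c[[t]], b)) + gram$yss[[t]]
    }, numeric(1)))
  }
  objective <- function(B) {
    obj_quad(B) + lambda1 * sum(abs(B)) + lambda2 * sum(sqrt(rowSums(B^2)))
  }

  trace <- numeric(max_iter + 1L)
  trace[1] <- objective(B)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    grad <- vapply(seq_len(d), function(t)
      gram$G[[t]] %*% B[, t] - gram$c[[t]], numeric(p))
    grad <- matrix(grad, p, d)
    B <- sgl_prox(B - s * grad, s * lambda1, s * lambda2)
    trace[it + 1L] <- objective(B)
    denom <- max(abs(trace[it]), 1e-12)
    if (abs(trace[it] - trace[it + 1L]) / denom < tol) {
      converged <- TRUE
      break
    }
  }
  structure(list(weights = B, objective_trace = trace[seq_len(it + 1L)],
                 converged = converged, n_iter = it,
                 lambda1 = lambda1, lambda2 = lambda2),
            class = "sgl_fit")
}

#' Precompute Gram-form sufficient statistics for [fit_sparse_group_lasso()]
#'
#' @inheritParams sgl_objective
#' @return List with `G`, `c`, `L`, `yss` (see
#'   [fit_sparse_group_lasso()]).
#' @export
sgl_gram <- function(X, Y) {
  d <- length(X)
  G <- vector("list", d); cc <- vector("list", d); yss <- vector("list", d)
  for (t in seq_len(d)) {
    N <- length(Y[[t]])
    G[[t]] <- crossprod(X[[t]]) / N
    cc[[t]] <- drop(crossprod(X[[t]], Y[[t]])) / N
    yss[[t]] <- sum(Y[[t]]^2) / (2 * N)
  }
  L <- max(vapply(G, function(g)
    max(eigen(g, symmetric = TRUE, only.values = TRUE)$values), numeric(1)))
  list(G = G, c = cc, L = max(L, 1e-12), yss = yss)
}

#' KKT residual of a sparse-group-LASSO solution
#'
#' Maximum violation of the first-order optimality conditions; used to
#' certify convergence (a correct minimizer has residual near 0).
#'
#' @param fit An `sgl_fit`.
#' @inheritParams sgl_objective
#' @return Scalar residual.
#' @export
sgl_kkt_residual <- function(fit, X, Y) {
  B <- fit$weights
  p <- nrow(B); d <- ncol(B)
  grad <- vapply(seq_len(d), function(t)
    crossprod(X[[t]], X[[t]] %*% B[, t] - Y[[t]]) / length(Y[[t]]),
    numeric(p))
  grad <- matrix(grad, p, d)
  l1 <- fit$lambda1; l2 <- fit$lambda2
  viol <- 0
  for (j in seq_len(p)) {
    bj <- B[j, ]; gj <- grad[j, ]
    rn <- sqrt(sum(bj^2))
    if (rn > 0) {
      sub <- gj + l1 * ifelse(bj != 0, sign(bj), 0) + l2 * bj / rn
      # zero coordinates inside an active row: l1 subgradient free in [-1,1]
      z <- bj == 0
      sub[z] <- pmax(abs(gj[z]) - l1, 0)
      viol <- max(viol, max(abs(sub)))
    } else {
      # whole row at zero: need dist(-g, l1*Linf-ball) <= l2 in L2
      resid <- pmax(abs(gj) - l1, 0)
      viol <- max(viol, max(sqrt(sum(resid^2)) - l2, 0))
    }
  }
  viol
}

#' @export
print.sgl_fit <- function(x, ...) {
  cat(sprintf(
    "<sgl_fit> %d SNPs x %d tissues; lambda1 = %.4g, lambda2 = %.4g; %s in %d iter\n",
    nrow(x$weights), ncol(x$weights), x$lambda1, x$lambda2,
    if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' @rdname fit_sparse_group_lasso
#' @param x An `sgl_fit`.
#' @param ... Unused.
#' @export
tidy.sgl_fit <- function(x, ...) {
  B <- x$weights
  tibble(snp = rep(rownames(B) %||% as.character(seq_len(nrow(B))),
                   ncol(B)),
         tissue = rep(colnames(B) %||% as.character(seq_len(ncol(B))),
                      each = nrow(B)),
         weight = as.vector(B))
}

#' @rdname fit_sparse_group_lasso
#' @export
glance.sgl_fit <- function(x, ...) {
  tibble(objective = x$objective_trace[length(x$objective_trace)],
         n_iter = x$n_iter, converged = x$converged,
         lambda1 = x$lambda1, lambda2 = x$lambda2,
         n_nonzero = sum(x$weights != 0))
}
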