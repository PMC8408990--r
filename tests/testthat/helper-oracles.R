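# Independent oracles used by the test suite. Each reimplements the
# quantity it checks from scratch (its own objective, its own densities),
# sharing no code path with the package implementation.

# -- sparse-group-LASSO objective, written out directly -----------------
oracle_sgl_objective <- function(B, X, Y, l1, l2) {
  loss <- 0
  for (t in seq_along(X)) {
    r <- Y[[t]] - X[[t]] %*% B[, t]
    loss <- loss + sum(r * r) / (2 * length(Y[[t]]))
  }
  pen1 <- l1 * sum(abs(B))
  pen2 <- l2 * sum(apply(B, 1, function(row) sqrt(sum(row * row))))
  loss + pen1 + pen2
}

# -- generic convex solver for the same problem: ADMM with over-relaxation
# (B-step: ridge solves; Z-step: the sparse-group proximal map, rederived
# here; consensus constraint B = Z)
oracle_sgl_admm <- function(X, Y, l1, l2, rho = 1, max_iter = 50000L,
                            tol = 1e-12) {
  d <- length(X)
  p <- ncol(X[[1]])
  G <- list(); cc <- list(); ch <- list()
  for (t in seq_len(d)) {
    N <- length(Y[[t]])
    G[[t]] <- crossprod(X[[t]]) / N
    cc[[t]] <- drop(crossprod(X[[t]], Y[[t]])) / N
    ch[[t]] <- chol(G[[t]] + diag(rho, p))
  }
  B <- matrix(0, p, d); Z <- B; U <- B
  alpha <- 1.7
  for (it in seq_len(max_iter)) {
    for (t in seq_len(d)) {
      rhs <- cc[[t]] + rho * (Z[, t] - U[, t])
      B[, t] <- backsolve(ch[[t]], backsolve(ch[[t]], rhs, transpose = TRUE))
    }
    Bh <- alpha * B + (1 - alpha) * Z
    W <- Bh + U
    Znew <- sign(W) * pmax(abs(W) - l1 / rho, 0)
    rn <- sqrt(rowSums(Znew^2))
    keep <- rn > 0
    Znew[keep, ] <- Znew[keep, , drop = FALSE] *
      pmax(1 - (l2 / rho) / rn[keep], 0)
    U <- U + Bh - Znew
    prim <- sqrt(sum((B - Znew)^2))
    dual <- rho * sqrt(sum((Znew - Z)^2))
    Z <- Znew
    if (prim < tol && dual < tol) break
  }
  Z
}

# -- full-dimensional Gaussian log-density ------------------------------
oracle_dmvnorm_log <- function(z, V) {
  ch <- chol(V)
  q <- drop(crossprod(backsolve(ch, z, transpose = TRUE)))
  -0.5 * (length(z) * log(2 * pi) + 2 * sum(log(diag(ch))) + q)
}

# -- fine-mapping by exhaustive enumeration with full-dimensional
# densities (no Woodbury shortcuts)
oracle_finemap_pips <- function(z, omega, p0 = 1e-3, v = 40, ridge = 0.1) {
  m <- length(z)
  S <- omega + diag(ridge, m)
  subsets <- lapply(0:(2^m - 1), function(code)
    which(bitwAnd(code, 2^(seq_len(m) - 1)) > 0))
  logpost <- vapply(subsets, function(cf) {
    V1 <- S
    if (length(cf) > 0)
      V1 <- S + v * S[, cf, drop = FALSE] %*% S[cf, , drop = FALSE]
    lbf <- oracle_dmvnorm_log(z, V1) - oracle_dmvnorm_log(z, S)
    lbf + length(cf) * log(p0) + (m - length(cf)) * log(1 - p0)
  }, numeric(1))
  w <- exp(logpost - max(logpost))
  post <- w / sum(w)
  pip <- numeric(m)
  for (i in seq_along(subsets)) pip[subsets[[i]]] <- pip[subsets[[i]]] + post[i]
  pip
}

# -- Monte-Carlo oracle for the copula-implied adjacent dosage correlation
oracle_ar1_dosage_cor <- function(maf1, maf2, rho, n_draws = 1e6,
                                  seed = 424242) {
  set.seed(seed)
  hap_pair <- function() {
    z1 <- rnorm(n_draws)
    z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n_draws)
    cbind(z1 < qnorm(maf1), z2 < qnorm(maf2)) * 1
  }
  d <- hap_pair() + hap_pair()
  cor(d[, 1], d[, 2])
}

# -- random positive-definite correlation matrix ------------------------
random_correlation <- function(m) {
  A <- matrix(rnorm(m * m), m)
  V <- crossprod(A) + diag(m) * 0.5
  D <- 1 / sqrt(diag(V))
  V * tcrossprod(D)
}

# -- small multi-tissue regression instances ----------------------------
make_sgl_instance <- function(n = 50, p = 5, d = 2, seed = 1) {
  set.seed(seed)
  X <- lapply(seq_len(d), function(t) {
    x <- matrix(rnorm(n * p), n, p)
    scale(x)[, , drop = FALSE] * sqrt(n / (n - 1))
  })
  beta <- matrix(rnorm(p * d, 0, 0.5) * rbinom(p * d, 1, 0.6), p, d)
  Y <- lapply(seq_len(d), function(t) {
    y <- drop(X[[t]] %*% beta[, t]) + rnorm(n)
    y - mean(y)
  })
  list(X = X, Y = Y, beta = beta)
}
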