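# Shared fixtures and independent oracles used across the suite. Oracles are
# deliberately written with dense linear algebra, independent of the
# spectral/MME code paths they check.

# Positive-definite relationship matrix with trace n (p > n guarantees full
# rank almost surely).
make_pd_grm <- function(n, seed = 1, p = n + 25) {
  set.seed(seed)
  Z <- matrix(rnorm(n * p), n, p)
  G <- tcrossprod(Z) / p
  G <- G * (n / sum(diag(G)))
  dimnames(G) <- list(sprintf("L%03d", 1:n), sprintf("L%03d", 1:n))
  (G + t(G)) / 2
}

# Dense REML log-likelihood for y = mu + u + e, u ~ N(0, s2p h2 G),
# e ~ N(0, s2p (1 - h2) I), total variance profiled out. Independent of the
# spectral implementation.
reml_ll_dense <- function(h2, y, G) {
  n <- length(y)
  H <- h2 * G + (1 - h2) * diag(n)
  X <- matrix(1, n, 1)
  Hi <- solve(H)
  XtHiX <- crossprod(X, Hi %*% X)
  beta <- solve(XtHiX, crossprod(X, Hi %*% y))
  r <- y - X %*% beta
  rss <- as.numeric(crossprod(r, Hi %*% r))
  s2p <- rss / (n - 1)
  as.numeric(-0.5 * ((n - 1) * (log(2 * pi * s2p) + 1) +
                       determinant(H)$modulus + log(det(XtHiX))))
}

# GLS oracle for multi-trait BLUP built literally from the joint covariance
# K (x) G + R (x) I over observed cells: fixed effects by GLS, genetic
# values as Cov(u, y) Sigma^{-1} (y - X mu).
kron_blup_oracle <- function(Y, G, K, R) {
  n <- nrow(Y); q <- ncol(Y)
  obs <- which(!is.na(as.numeric(Y)))          # column-major = vec(Y)
  yv <- as.numeric(Y)[obs]
  Sig_full <- kronecker(K, G) + kronecker(R, diag(n))
  Sig <- Sig_full[obs, obs, drop = FALSE]
  X_full <- kronecker(diag(q), matrix(1, n, 1))
  X <- X_full[obs, , drop = FALSE]
  Si <- solve(Sig)
  mu <- solve(crossprod(X, Si %*% X), crossprod(X, Si %*% yv))
  Cu <- kronecker(K, G)[, obs, drop = FALSE]
  u <- as.numeric(Cu %*% (Si %*% (yv - X %*% mu)))
  U <- matrix(u, n, q, dimnames = dimnames(Y))
  list(mu = as.numeric(mu), U = U,
       predictions = sweep(U, 2, as.numeric(mu), "+"))
}

# Small balanced plot table with known genotype effects and IID design
# effects, for adjustment tests.
make_small_trial <- function(n_geno = 6, n_rep = 2, n_block = 2,
                             rep_sd = 0.5, block_sd = 0.5, res_sd = 0.3,
                             geno_eff = NULL, seed = 1) {
  set.seed(seed)
  genos <- sprintf("g%02d", 1:n_geno)
  if (is.null(geno_eff)) geno_eff <- setNames(rnorm(n_geno, 10, 2), genos)
  recs <- list()
  for (r in 1:n_rep) {
    blocks <- rep_len(1:n_block, n_geno)[sample(n_geno)]
    re <- rnorm(1, 0, rep_sd)
    be <- rnorm(n_block, 0, block_sd)
    recs[[r]] <- data.frame(env = "E1", rep = paste0("R", r),
                            block = paste0("B", blocks), genotype = genos,
                            y = geno_eff + re + be[blocks] +
                              rnorm(n_geno, 0, res_sd),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  attr(out, "geno_eff") <- geno_eff
  out
}
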