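# Multi-trait GBLUP with Kronecker covariance: vec(U) ~ MVN(0, K (x) G),
# residual rows ~ MVN(0, R). Fitting is Bayesian (Gibbs sampler with
# inverse-Wishart updates, data augmentation of missing/masked cells);
# mt_blup_given_vc solves the mixed-model equations at fixed (K, R).

#' Gibbs chain settings for the multi-trait sampler
#'
#' @param n_iter Total iterations (default 12000).
#' @param burnin Burn-in iterations discarded (default 2000).
#' @param thin Thinning interval for retained samples (default 5).
#' @param nu_margin Added to `q` to form the inverse-Wishart prior degrees of
#'   freedom `nu = q + nu_margin` (default 4, weakly informative).
#' @param prior_share Fraction of the observed phenotypic covariance assigned
#'   to the prior mean of each of `K` and `R` (default 0.5).
#' @return A list of class `mt_chain`.
#' @export
mt_chain <- function(n_iter = 12000L, burnin = 2000L, thin = 5L,
                     nu_margin = 4, prior_share = 0.5) {
  if (burnin >= n_iter) {
    stop("chain shorter than burn-in: n_iter must exceed burnin",
         call. = FALSE)
  }
  if (thin < 1L) stop("`thin` must be >= 1", call. = FALSE)
  structure(list(n_iter = as.integer(n_iter), burnin = as.integer(burnin),
                 thin = as.integer(thin), nu_margin = nu_margin,
                 prior_share = prior_share),
            class = "mt_chain")
}

# Eigenvalues of G clipped at a small positive floor so that G^{-1} exists
# (a column-centered GRM is singular in the direction of the all-ones
# vector); equivalent to an infinitesimal ridge on G.
grm_eigen <- function(G, floor_rel = 1e-8) {
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  dmax <- max(e$values, 0)
  if (min(e$values) < -1e-8 * max(dmax, 1)) {
    stop("relationship matrix is not PSD", call. = FALSE)
  }
  e$values <- pmax(e$values, floor_rel * max(dmax, 1))
  e
}

#' Fit multi-trait GBLUP by Gibbs sampling
#'
#' Samples, in turn: unobserved cells from their conditional normal given the
#' observed traits of the same line (data augmentation, which is what makes
#' cross-validation predictions emerge naturally); genetic values given
#' (K, R) in the eigenbasis of `G`; `K` and `R` from inverse-Wishart full
#' conditionals; and per-column intercepts. Priors are inverse-Wishart with
#' `nu = q + nu_margin` degrees of freedom and scale chosen so the prior
#' mean of each of `K` and `R` equals `prior_share` times the phenotypic
#' covariance of the observed columns.
#'
#' @param Y n x q numeric matrix of responses (adjusted means); `NA` marks
#'   unobserved or masked cells. Column names label the traits.
#' @param G n x n relationship matrix aligned with the rows of `Y`.
#' @param chain An [mt_chain()] settings object.
#' @param seed Integer seed (the chain is deterministic given it).
#' @return Object of class `mt_gblup`: posterior means and SDs of `K` and
#'   `R`, `mu` (per-column intercepts), `h2` and `h2_sd`, genetic correlation
#'   matrix `rg` with `rg_sd`, `predictions` (posterior mean of `mu + u` for
#'   every cell, masked ones included) with `predictions_sd`, per-sample
#'   `h2_samples`/`rg_samples`, and the chain settings.
#' @export
fit_mt_gblup <- function(Y, G, chain = mt_chain(), seed = 1L) {
  Y <- as.matrix(Y)
  q <- ncol(Y)
  n <- nrow(Y)
  if (q < 1L) stop("`Y` needs at least one column", call. = FALSE)
  if (nrow(G) != n) stop("`G` must align with the rows of `Y`", call. = FALSE)
  obs <- !is.na(Y)
  if (any(colSums(obs) < 2L)) {
    stop("every column needs at least two observed cells", call. = FALSE)
  }
  traits <- colnames(Y)
  if (is.null(traits)) traits <- paste0("T", seq_len(q))

  # prior scale from the phenotypic covariance of observed columns
  Sp <- stats::cov(Y, use = "pairwise.complete.obs")
  Sp[!is.finite(Sp)] <- 0
  diag(Sp)[diag(Sp) <= 0] <- stats::var(as.numeric(Y), na.rm = TRUE)
  ev <- eigen((Sp + t(Sp)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8 * max(ev)) {
    Sp <- Sp + diag(1e-6 * max(diag(Sp)), q)   # guard a degenerate prior
  }
  nu <- q + chain$nu_margin
  Psi <- (nu - q - 1) * chain$prior_share * Sp

  e <- grm_eigen(G)
  Yz <- Y
  Yz[!obs] <- 0
  set.seed(seed)
  res <- mt_gibbs_cpp(Yz, matrix(as.integer(obs), n, q), e$vectors, e$values,
                      Psi, nu, Psi, nu,
                      chain$n_iter, chain$burnin, chain$thin)
  K <- res$K_mean
  R <- res$R_mean
  dimnames(K) <- dimnames(R) <- dimnames(res$K_sd) <- dimnames(res$R_sd) <-
    list(traits, traits)
  hf <- heritability_from_fit(K, R)
  preds <- res$pred_mean
  dimnames(preds) <- dimnames(res$pred_sd) <- list(rownames(Y), traits)
  h2_samp <- res$h2_samples
  colnames(h2_samp) <- traits
  structure(list(K = K, K_sd = res$K_sd, R = R, R_sd = res$R_sd,
                 mu = stats::setNames(as.numeric(res$mu_mean), traits),
                 h2 = hf$h2,
                 h2_sd = apply(h2_samp, 2, stats::sd),
                 rg = hf$rg,
                 rg_sd = offdiag_to_matrix(
                   if (q >= 2) apply(res$rg_samples, 2, stats::sd)
                   else numeric(0), q, traits),
                 predictions = preds, predictions_sd = res$pred_sd,
                 h2_samples = h2_samp, rg_samples = res$rg_samples,
                 n_saved = res$n_saved, chain = chain, seed = seed),
            class = "mt_gblup")
}

# Expand a vector of upper-triangle (by row) values into a symmetric matrix
# with NA diagonal.
offdiag_to_matrix <- function(v, q, traits) {
  M <- matrix(NA_real_, q, q, dimnames = list(traits, traits))
  c <- 1L
  if (q >= 2) for (a in 1:(q - 1)) for (b in (a + 1):q) {
    M[a, b] <- M[b, a] <- v[c]
    c <- c + 1L
  }
  M
}

#' @export
print.mt_gblup <- function(x, ...) {
  q <- ncol(x$K)
  cat("mt_gblup fit:", q, "columns,", x$n_saved, "retained samples\n")
  cat("posterior mean h2:", paste(sprintf("%s = %.3f", names(x$h2), x$h2),
                                  collapse = ", "), "\n")
  if (q >= 2) {
    cat("genetic correlations (lower triangle):\n")
    print(round(x$rg, 3))
  }
  invisible(x)
}

#' Heritability and genetic correlations from trait covariance matrices
#'
#' Line-basis heritabilities are the diagonal of the elementwise ratio
#' `K / (K + R)`; genetic correlations are `K[j,k] / sqrt(K[j,j] K[k,k])`.
#'
#' @param K,R q x q genetic and residual covariance matrices.
#' @return List with `h2` (named vector) and `rg` (correlation matrix with
#'   unit diagonal).
#' @export
heritability_from_fit <- function(K, R) {
  K <- as.matrix(K)
  R <- as.matrix(R)
  tot <- diag(K) + diag(R)
  if (any(tot <= 0)) {
    stop("zero total variance on a diagonal; heritability undefined",
         call. = FALSE)
  }
  h2 <- diag(K) / tot
  s <- sqrt(diag(K))
  rg <- K / tcrossprod(pmax(s, .Machine$double.eps))
  diag(rg) <- 1
  traits <- colnames(K)
  if (!is.null(traits)) {
    names(h2) <- traits
    dimnames(rg) <- list(traits, traits)
  }
  list(h2 = h2, rg = rg)
}

#' Multi-trait BLUP at fixed variance components
#'
#' Solves Henderson's mixed-model equations for the model
#' `y = X mu + Z u + e` over the observed cells only, with
#' `u = vec(U) ~ MVN(0, K (x) G)` and residuals correlated across traits
#' within a line (`R` restricted to each line's observed pattern). Every
#' cell's prediction is its column intercept plus the corresponding genetic
#' value.
#'
#' @param Y n x q response matrix with `NA` for unobserved/masked cells.
#' @param G n x n relationship matrix (near-singular directions are ridged
#'   by an infinitesimal eigenvalue floor so that `G^{-1}` exists).
#' @param K,R q x q genetic and residual covariance matrices (`R` must be
#'   invertible on every observed pattern).
#' @return List with `mu` (GLS intercepts), `U` (n x q genetic values) and
#'   `predictions` (`mu[j] + U[i,j]` for all cells).
#' @export
mt_blup_given_vc <- function(Y, G, K, R) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  q <- ncol(Y)
  K <- as.matrix(K)
  R <- as.matrix(R)
  obs <- !is.na(Y)
  if (any(colSums(obs) < 1L)) {
    stop("every column needs at least one observed cell", call. = FALSE)
  }
  e <- grm_eigen(G)
  Ginv <- e$vectors %*% (t(e$vectors) / e$values)
  Kinv <- solve(K)

  p <- q + n * q                       # unknowns: q intercepts, then vec(U)
  C <- matrix(0, p, p)
  rhs <- numeric(p)
  for (i in seq_len(n)) {
    o <- which(obs[i, ])
    if (!length(o)) next
    Roo <- R[o, o, drop = FALSE]
    Wi <- tryCatch(solve(Roo), error = function(e)
      stop("residual covariance singular on the observed pattern of line ",
           i, call. = FALSE))
    upos <- (o - 1L) * n + i           # u_{i,j} position within vec(U)
    mpos <- o
    yi <- Y[i, o]
    idx <- c(mpos, q + upos)
    # design rows: both the intercept and the genetic value enter with
    # coefficient 1, so all four blocks share the same W^{-1} kernel
    blk <- rbind(cbind(Wi, Wi), cbind(Wi, Wi))
    C[idx, idx] <- C[idx, idx] + blk
    rhs[idx] <- rhs[idx] + rep(as.numeric(Wi %*% yi), 2L)
  }
  C[(q + 1):p, (q + 1):p] <- C[(q + 1):p, (q + 1):p] + kronecker(Kinv, Ginv)
  sol <- solve(C, rhs)
  mu <- sol[seq_len(q)]
  U <- matrix(sol[-seq_len(q)], n, q)
  dimnames(U) <- dimnames(Y)
  names(mu) <- colnames(Y)
  preds <- sweep(U, 2L, mu, "+")
  list(mu = mu, U = U, predictions = preds)
}
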