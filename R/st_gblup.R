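# Single-trait GBLUP: y = mu + u + e with u ~ MVN(0, sigma2_u * G) and
# e ~ MVN(0, sigma2_e * I). REML via one spectral decomposition of G and a
# 1-D Brent search over heritability (all likelihood evaluations are O(n)
# after the eigendecomposition).

#' Fit single-trait GBLUP by REML
#'
#' Eigendecomposes the relationship matrix once, rotates the response into
#' the eigenbasis, and profiles the restricted log-likelihood over
#' `h2 = sigma2_u / (sigma2_u + sigma2_e)` with Brent optimization on
#' `[1e-5, 1 - 1e-5]` (boundary optima are reported as such). The total
#' variance is profiled analytically. `G` is trace-normalized internally, so
#' `h2`, BLUPs and predictions are invariant to the overall scale of `G`
#' while the reported `sigma2_u` refers to the scale of the supplied matrix.
#'
#' @param y Numeric response vector (adjusted means), length n; names, if
#'   present, must match `rownames(G)`.
#' @param G n x n symmetric PSD relationship matrix.
#' @return Object of class `st_gblup`: `mu` (GLS intercept), `sigma2_u`,
#'   `sigma2_e`, `h2`, `u_hat` (BLUPs for all n lines), `loglik` (REML
#'   log-likelihood at the optimum) and `boundary` (TRUE when the optimum is
#'   at either end of the `h2` interval).
#' @export
fit_st_gblup <- function(y, G) {
  y <- as.numeric(y)
  n <- length(y)
  if (any(!is.finite(y))) stop("`y` contains non-finite values", call. = FALSE)
  if (nrow(G) != n) stop("length(y) must match nrow(G)", call. = FALSE)
  if (stats::var(y) == 0) stop("`y` is constant; heritability is undefined",
                               call. = FALSE)
  gscale <- n / sum(diag(G))
  e <- eigen((G + t(G)) / 2 * gscale, symmetric = TRUE)
  d <- pmax(e$values, 0)
  V <- e$vectors
  yt <- crossprod(V, y)
  xt <- crossprod(V, rep(1, n))

  negll <- function(h2) -reml_ll_spectral(h2, d, yt, xt, n)
  opt <- stats::optimize(negll, interval = c(1e-5, 1 - 1e-5), tol = 1e-9)
  h2 <- opt$minimum
  parts <- reml_ll_spectral(h2, d, yt, xt, n, parts = TRUE)
  s2p <- parts$s2p
  w <- h2 * d + (1 - h2)
  u_hat <- V %*% ((h2 * d / w) * (yt - xt * parts$mu))
  structure(list(mu = parts$mu,
                 sigma2_u = h2 * s2p * gscale,
                 sigma2_e = (1 - h2) * s2p,
                 h2 = h2,
                 u_hat = stats::setNames(as.numeric(u_hat), rownames(G)),
                 loglik = parts$ll,
                 boundary = h2 <= 2e-5 || h2 >= 1 - 2e-5),
            class = "st_gblup")
}

# Profiled REML log-likelihood in the eigenbasis of the (trace-normalized)
# relationship matrix: w_i = h2 d_i + (1 - h2), intercept by GLS, total
# variance profiled as rss / (n - 1).
reml_ll_spectral <- function(h2, d, yt, xt, n, parts = FALSE) {
  w <- h2 * d + (1 - h2)
  xw <- sum(xt^2 / w)
  mu <- sum(xt * yt / w) / xw
  rss <- sum((yt - xt * mu)^2 / w)
  s2p <- rss / (n - 1)
  ll <- -0.5 * ((n - 1) * (log(2 * pi * s2p) + 1) + sum(log(w)) + log(xw))
  if (parts) list(ll = ll, mu = mu, s2p = s2p) else ll
}

#' @export
print.st_gblup <- function(x, ...) {
  cat(sprintf(
    "st_gblup fit: h2 = %.3f (sigma2_u = %.4g, sigma2_e = %.4g), mu = %.4g%s\n",
    x$h2, x$sigma2_u, x$sigma2_e, x$mu,
    if (x$boundary) " [boundary]" else ""))
  invisible(x)
}

#' Predict test lines from a training-set GBLUP fit
#'
#' Fits ST-GBLUP on the training lines only (unless a shrinkage parameter is
#' supplied) and predicts the test lines through their genomic relationships:
#' `yhat = mu + G[test, train] solve(G[train, train] + lambda I) (y_train - mu)`
#' with `lambda = sigma2_e / sigma2_u` from the training fit and `mu` the GLS
#' intercept on the training data.
#'
#' @param y Named response vector covering at least the training lines, or a
#'   full-length vector aligned with `rownames(G)`.
#' @param G Relationship matrix over all lines.
#' @param train_ids,test_ids Disjoint subsets of `rownames(G)`.
#' @param lambda Optional fixed variance ratio `sigma2_e / sigma2_u`;
#'   when supplied no REML fit is performed (used for variance-components-
#'   given prediction and for limiting-case checks).
#' @return Named numeric vector of predictions for `test_ids`, with the
#'   training fit attached as attribute `"fit"` (NULL when `lambda` given).
#' @export
predict_st <- function(y, G, train_ids, test_ids, lambda = NULL) {
  ids <- rownames(G)
  if (is.null(ids)) {
    ids <- as.character(seq_len(nrow(G)))
    dimnames(G) <- list(ids, ids)
  }
  if (is.null(names(y))) {
    if (length(y) != nrow(G)) stop("unnamed `y` must align with `G`",
                                   call. = FALSE)
    names(y) <- ids
  }
  train_ids <- as.character(train_ids)
  test_ids <- as.character(test_ids)
  if (!length(train_ids)) stop("empty training set", call. = FALSE)
  if (length(intersect(train_ids, test_ids))) {
    stop("training and test sets overlap", call. = FALSE)
  }
  if (!all(c(train_ids, test_ids) %in% ids)) {
    stop("train/test ids not all present in `G`", call. = FALSE)
  }
  ytr <- y[train_ids]
  Gtt <- G[train_ids, train_ids, drop = FALSE]
  fit <- NULL
  if (is.null(lambda)) {
    fit <- fit_st_gblup(ytr, Gtt)
    lambda <- fit$sigma2_e / fit$sigma2_u
    mu <- fit$mu
  } else {
    if (is.infinite(lambda)) {
      mu <- mean(ytr)
      out <- stats::setNames(rep(mu, length(test_ids)), test_ids)
      return(structure(out, fit = NULL))
    }
    A <- Gtt + diag(lambda, length(train_ids))
    one <- rep(1, length(train_ids))
    Ai1 <- solve(A, one)
    mu <- sum(Ai1 * ytr) / sum(Ai1 * one)
  }
  alpha <- solve(Gtt + diag(lambda, length(train_ids)), ytr - mu)
  pred <- mu + as.numeric(G[test_ids, train_ids, drop = FALSE] %*% alpha)
  structure(stats::setNames(pred, test_ids), fit = fit)
}
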