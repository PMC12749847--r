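# Design adjustment: least-squares means against a direct GLS oracle at the
# REML variance estimates, the REML optimum against a dense grid search, and
# the algebraic limits that must hold exactly.

test_that("balanced noise-free data returns raw genotype means", {
  tr <- make_small_trial(n_geno = 8, rep_sd = 0, block_sd = 0, res_sd = 0,
                         seed = 2)
  a <- fit_within_env(tr, "y", "E1")
  raw <- tapply(tr$y, tr$genotype, mean)
  expect_equal(a$means[names(raw)], raw, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(unname(a$varcomp["residual"]), 0, tolerance = 1e-8)
})

test_that("within-environment adjusted means match a GLS oracle at the REML estimates", {
  tr <- make_small_trial(n_geno = 6, n_rep = 2, n_block = 2, seed = 3)
  a <- fit_within_env(tr, "y", "E1")

  # dense GLS with the explicit covariance of the fitted model
  Zr <- model.matrix(~ 0 + factor(rep), tr)
  grp <- interaction(tr$rep, tr$block, drop = TRUE)
  Zb <- model.matrix(~ 0 + grp)
  X <- model.matrix(~ 0 + factor(genotype), tr)
  V <- a$varcomp["rep"] * tcrossprod(Zr) +
    a$varcomp["rep:block"] * tcrossprod(Zb) +
    a$varcomp["residual"] * diag(nrow(tr))
  Vi <- solve(V)
  blue <- solve(crossprod(X, Vi %*% X), crossprod(X, Vi %*% tr$y))
  expect_equal(as.numeric(a$means[sort(unique(tr$genotype))]),
               as.numeric(blue), tolerance = 1e-6)
})

test_that("adding a constant shifts every adjusted mean by that constant", {
  tr <- make_small_trial(n_geno = 6, seed = 4)
  a1 <- fit_within_env(tr, "y", "E1")
  tr2 <- tr
  tr2$y <- tr$y + 11.5
  a2 <- fit_within_env(tr2, "y", "E1")
  expect_equal(a2$means, a1$means + 11.5, tolerance = 1e-7)
})

test_that("REML variance components beat a dense grid on the profiled likelihood", {
  tr <- make_small_trial(n_geno = 10, n_rep = 3, n_block = 2, seed = 6)
  expect_equal(nrow(tr), 30)
  a <- fit_within_env(tr, "y", "E1")

  X <- model.matrix(~ 0 + factor(genotype), tr)
  Zr <- model.matrix(~ 0 + factor(rep), tr)
  grp <- interaction(tr$rep, tr$block, drop = TRUE)
  Zb <- model.matrix(~ 0 + grp)
  n <- nrow(tr)
  p <- ncol(X)
  # profiled REML log-likelihood over variance ratios (gr, gb)
  prof_ll <- function(gr, gb) {
    H <- diag(n) + gr * tcrossprod(Zr) + gb * tcrossprod(Zb)
    Hi <- solve(H)
    XtHiX <- crossprod(X, Hi %*% X)
    beta <- solve(XtHiX, crossprod(X, Hi %*% tr$y))
    r <- tr$y - X %*% beta
    rss <- as.numeric(crossprod(r, Hi %*% r))
    s2 <- rss / (n - p)
    -0.5 * ((n - p) * (log(2 * pi * s2) + 1) +
              as.numeric(determinant(H)$modulus) +
              as.numeric(determinant(XtHiX)$modulus))
  }
  ll_hat <- prof_ll(a$varcomp["rep"] / a$varcomp["residual"],
                    a$varcomp["rep:block"] / a$varcomp["residual"])
  grid <- seq(0, 3, by = 0.05)
  ll_grid <- outer(grid, grid, Vectorize(prof_ll))
  expect_lt(max(ll_grid), ll_hat + 1e-4)
})

test_that("across-environment means on balanced data average the within-environment means", {
  set.seed(8)
  genos <- sprintf("g%02d", 1:10)
  geno_eff <- rnorm(10, 20, 3)
  recs <- list()
  for (e in 1:3) for (r in 1:2) {
    recs[[length(recs) + 1]] <- data.frame(
      env = paste0("E", e), year = 2020 + e, rep = paste0("R", r),
      block = "B1", genotype = genos,   # complete blocks keep the design
      y = geno_eff + rnorm(1, 0, 1) + rnorm(10, 0, 0.5),  # orthogonal
      stringsAsFactors = FALSE)
  }
  plots <- do.call(rbind, recs)
  acr <- fit_across_env(plots, "y")
  withins <- sapply(paste0("E", 1:3),
                    function(e) fit_within_env(plots, "y", e)$means)
  expect_equal(as.numeric(acr$means), as.numeric(rowMeans(withins)),
               tolerance = 1e-6)
  expect_true(acr$connected)
})

test_that("disjoint genotype sets across environments are flagged as unconnected", {
  recs <- rbind(
    data.frame(env = "E1", year = 2020, rep = "R1", block = "B1",
               genotype = c("a", "b", "c"), y = c(1, 2, 3)),
    data.frame(env = "E2", year = 2021, rep = "R1", block = "B1",
               genotype = c("d", "e", "f"), y = c(4, 5, 6)))
  recs <- rbind(recs, transform(recs, rep = "R2", y = y + 0.1))
  expect_warning(a <- fit_across_env(recs, "y"), "unconnected")
  expect_false(a$connected)
})

test_that("adjusted means recover known genotype effects under replication", {
  cfg <- sim_config(n_lines = 60, n_snps = 10, K_true = diag(c(1, 1)),
                    R_true = diag(c(0.3, 0.3)), n_envs = 3, n_reps = 3,
                    n_blocks = 4, env_var = 1, rep_var = 0.3,
                    block_var = 0.3, missing_rate = 0, seed = 44)
  U <- simulate_genetic_values(diag(60), diag(c(1, 1)), seed = 45)
  rownames(U) <- sprintf("L%03d", 1:60)
  plots <- simulate_trial(U, cfg)
  acr <- fit_across_env(plots, "T1")
  common <- intersect(names(acr$means), rownames(U))
  expect_gt(cor(acr$means[common], U[common, 1], method = "spearman"), 0.95)
  expect_true(all(acr$varcomp >= 0))
  expect_gt(acr$varcomp["residual"], 0)
})

test_that("adjustment output is invariant to record order", {
  tr <- make_small_trial(n_geno = 7, seed = 10)
  a1 <- fit_within_env(tr, "y", "E1")
  set.seed(1)
  a2 <- fit_within_env(tr[sample(nrow(tr)), ], "y", "E1")
  expect_equal(a1$means, a2$means, tolerance = 1e-8)
  expect_equal(a1$varcomp, a2$varcomp, tolerance = 1e-6)
})

test_that("within-year environment factor uses the year term", {
  cfg <- sim_config(n_lines = 30, n_snps = 10, n_envs = 4, n_reps = 2,
                    n_blocks = 3, missing_rate = 0, seed = 50)
  U <- simulate_genetic_values(diag(30), cfg$K_true, seed = 51)
  rownames(U) <- sprintf("L%03d", 1:30)
  plots <- simulate_trial(U, cfg)
  one_loc <- plots[plots$location == "LOC1", ]
  expect_gt(length(unique(one_loc$year)), 1)
  a <- fit_across_env(one_loc, "Fe", env_factor = "year")
  expect_identical(a$env_factor, "year")
  expect_true(all(c("env", "env:rep", "genotype:env", "residual") %in%
                    names(a$varcomp)))
})

test_that("complete-case filtering drops exactly the lines with gaps", {
  M <- matrix(rnorm(20), 5, 4,
              dimnames = list(paste0("l", 1:5), paste0("c", 1:4)))
  M2 <- M
  M2[2, 3] <- NA
  expect_identical(rownames(complete_case_filter(M2)),
                   rownames(M)[-2])
  expect_identical(complete_case_filter(M), M)

  # the study-shaped case: 245 lines, 4 columns, 20 lines incomplete -> 225
  set.seed(60)
  big <- matrix(rnorm(245 * 4), 245, 4,
                dimnames = list(sprintf("L%03d", 1:245), NULL))
  gappy <- sample(245, 20)
  big[cbind(gappy, sample(4, 20, replace = TRUE))] <- NA
  expect_equal(nrow(complete_case_filter(big)), 225)

  allna <- matrix(NA_real_, 3, 2)
  expect_error(complete_case_filter(allna), "no line")
})
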