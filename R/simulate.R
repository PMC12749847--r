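# Synthetic-data generator: genotypes, genetic values and plot-level
# multi-environment phenotypes drawn from the generative model that the
# downstream GBLUP machinery assumes.

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generator. Defaults describe
#' a sorghum-minicore-sized study: 245 lines genotyped at 12,000 SNPs, grown
#' in alpha-lattice trials with 21 incomplete blocks and two replications in
#' each of two environments, with two correlated micronutrient traits of
#' moderately high heritability.
#'
#' Trait (co)variances are stated on the adjusted-phenotype scale with unit
#' total variance per trait, so `K_true[j, j]` is directly the line-basis
#' heritability of trait `j` when `R_true[j, j] = 1 - K_true[j, j]`.
#'
#' @param n_lines Number of lines (genotypes).
#' @param n_snps Number of biallelic SNPs.
#' @param maf_range Length-2 numeric in (0, 0.5]; per-SNP allele frequencies
#'   are drawn uniformly from this interval.
#' @param K_true q x q genetic variance-covariance matrix between traits
#'   (symmetric positive semi-definite). Column names, if any, become trait
#'   names.
#' @param R_true q x q residual variance-covariance matrix (symmetric PSD).
#' @param n_envs,n_reps,n_blocks Numbers of environments, replicates per
#'   environment and incomplete blocks per replicate.
#' @param env_var,rep_var,block_var Variances of the IID normal environment,
#'   replicate-within-environment and block-within-replicate effects
#'   (trait units squared).
#' @param ge_var Variance of the optional genotype-by-environment deviation,
#'   IID normal per (line, environment, trait). Default 0 (no G x E).
#' @param missing_rate Fraction of genotype calls set to missing, in [0, 1).
#' @param trait_means Optional numeric vector of overall trait means
#'   (default 0).
#' @param seed Integer RNG seed (mandatory for reproducibility).
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_genotypes()], [simulate_genetic_values()],
#'   [simulate_trial()]
#' @export
sim_config <- function(n_lines = 245L, n_snps = 12000L,
                       maf_range = c(0.05, 0.5),
                       K_true = default_K(), R_true = default_R(),
                       n_envs = 2L, n_reps = 2L, n_blocks = 21L,
                       env_var = 1, rep_var = 0.25, block_var = 0.25,
                       ge_var = 0, missing_rate = 0.05,
                       trait_means = NULL, seed = 1L) {
  cfg <- list(n_lines = as.integer(n_lines), n_snps = as.integer(n_snps),
              maf_range = as.numeric(maf_range),
              K_true = as.matrix(K_true), R_true = as.matrix(R_true),
              n_envs = as.integer(n_envs), n_reps = as.integer(n_reps),
              n_blocks = as.integer(n_blocks),
              env_var = env_var, rep_var = rep_var, block_var = block_var,
              ge_var = ge_var, missing_rate = missing_rate,
              trait_means = trait_means, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

# Default q = 2 trait world: two micronutrient traits, h2 = (0.6, 0.6),
# genetic correlation 0.9, mild residual correlation, unit total variance.
default_K <- function() {
  K <- matrix(c(0.6, 0.9 * 0.6, 0.9 * 0.6, 0.6), 2, 2)
  dimnames(K) <- list(c("Fe", "Zn"), c("Fe", "Zn"))
  K
}
default_R <- function() {
  R <- matrix(c(0.4, 0.3 * 0.4, 0.3 * 0.4, 0.4), 2, 2)
  dimnames(R) <- list(c("Fe", "Zn"), c("Fe", "Zn"))
  R
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (length(cfg$maf_range) != 2L || any(!is.finite(cfg$maf_range)) ||
      cfg$maf_range[1] > cfg$maf_range[2] ||
      cfg$maf_range[1] <= 0 || cfg$maf_range[2] > 0.5) {
    stop("`maf_range` must be an increasing pair within (0, 0.5]",
         call. = FALSE)
  }
  if (cfg$n_lines < 2L) stop("`n_lines` must be >= 2", call. = FALSE)
  if (cfg$n_snps < 1L) stop("`n_snps` must be >= 1", call. = FALSE)
  if (cfg$n_reps < 1L || cfg$n_blocks < 1L || cfg$n_envs < 1L) {
    stop("`n_envs`, `n_reps` and `n_blocks` must all be >= 1", call. = FALSE)
  }
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    stop("`missing_rate` must lie in [0, 1)", call. = FALSE)
  }
  q <- nrow(cfg$K_true)
  if (!isTRUE(all.equal(dim(cfg$K_true), dim(cfg$R_true)))) {
    stop("`K_true` and `R_true` must have the same dimension", call. = FALSE)
  }
  check_psd(cfg$K_true, "K_true")
  check_psd(cfg$R_true, "R_true")
  if (ncol(cfg$K_true) != q) stop("`K_true` must be square", call. = FALSE)
  if (is.null(colnames(cfg$K_true))) {
    colnames(cfg$K_true) <- rownames(cfg$K_true) <- paste0("T", seq_len(q))
    colnames(cfg$R_true) <- rownames(cfg$R_true) <- colnames(cfg$K_true)
  }
  if (is.null(cfg$trait_means)) cfg$trait_means <- rep(0, q)
  if (length(cfg$trait_means) != q) {
    stop("`trait_means` must have one entry per trait", call. = FALSE)
  }
  for (v in c("env_var", "rep_var", "block_var", "ge_var")) {
    if (cfg[[v]] < 0) stop("`", v, "` must be non-negative", call. = FALSE)
  }
  if (length(cfg$seed) != 1L || is.na(cfg$seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  cfg
}

check_psd <- function(M, name, tol = 1e-8) {
  if (max(abs(M - t(M))) > tol * max(1, max(abs(M)))) {
    stop("`", name, "` must be symmetric", call. = FALSE)
  }
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * max(1, max(abs(ev)))) {
    stop("`", name, "` must be positive semi-definite", call. = FALSE)
  }
  invisible(M)
}

#' Read a simulation configuration from a YAML file
#'
#' Scalars map to the arguments of [sim_config()]; `K_true` and `R_true` are
#' given as lists of rows. The `seed` key is mandatory.
#'
#' @param path Path to a YAML file.
#' @return A `sim_config` object.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$seed)) stop("simulation config must set `seed`",
                              call. = FALSE)
  for (m in c("K_true", "R_true")) {
    if (!is.null(raw[[m]])) raw[[m]] <- do.call(rbind, raw[[m]])
  }
  if (!is.null(raw$maf_range)) raw$maf_range <- unlist(raw$maf_range)
  do.call(sim_config, raw)
}

#' Symmetric matrix square root
#'
#' Eigendecomposition-based square root used for sampling from matrix-variate
#' normals. Eigenvalues below `-tol` (relative to the largest) are rejected as
#' non-PSD; small negative eigenvalues above that are clipped to zero.
#'
#' @param M Symmetric PSD matrix.
#' @param tol Relative tolerance for negative eigenvalues (default 1e-8).
#' @return A symmetric matrix `S` with `S %*% S = M`.
#' @keywords internal
matrix_sqrt <- function(M, tol = 1e-8) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  scale <- max(abs(e$values), 1e-300)
  if (min(e$values) < -tol * scale) {
    stop("matrix is not positive semi-definite (eigenvalue ",
         format(min(e$values)), ")", call. = FALSE)
  }
  d <- pmax(e$values, 0)
  e$vectors %*% (sqrt(d) * t(e$vectors))
}

#' Simulate a line x SNP dosage matrix
#'
#' Each SNP gets an allele frequency drawn uniformly from
#' `config$maf_range`; dosages (copies of the reference allele, 0/1/2) are
#' independent Binomial(2, freq) across lines, i.e. linkage equilibrium and
#' Hardy-Weinberg proportions. A `missing_rate` fraction of calls is then set
#' to `NA` uniformly at random.
#'
#' @param config A [sim_config()] object.
#' @param seed RNG seed; defaults to `config$seed`.
#' @return A [genotype_matrix()] with dimnames `L1..Ln` x `S1..Sp`.
#' @export
simulate_genotypes <- function(config, seed = config$seed) {
  config <- validate_sim_config(config)
  set.seed(seed)
  n <- config$n_lines
  p <- config$n_snps
  freq <- stats::runif(p, config$maf_range[1], config$maf_range[2])
  dos <- matrix(stats::rbinom(n * p, 2L, rep(freq, each = n)), nrow = n)
  if (config$missing_rate > 0) {
    dos[stats::runif(n * p) < config$missing_rate] <- NA_integer_
  }
  genotype_matrix(dos,
                  line_ids = sprintf("L%03d", seq_len(n)),
                  snp_ids = sprintf("S%05d", seq_len(p)))
}

#' Simulate genetic values from the multi-trait GBLUP prior
#'
#' Draws an n x q matrix `U` of genetic values with
#' `vec(U) ~ MVN(0, K_true (x) G)` where `(x)` is the Kronecker product:
#' columns are traits, rows are lines, trait covariance `K_true` and
#' line covariance `G`. Realized as `U = L_G %*% E %*% t(L_K)` with `E`
#' standard normal and `L_G`, `L_K` symmetric matrix square roots.
#'
#' @param G n x n genomic relationship matrix (symmetric PSD).
#' @param K_true q x q genetic covariance between traits (symmetric PSD).
#' @param seed Integer RNG seed.
#' @return n x q numeric matrix of genetic values; rows named after `G`'s
#'   lines, columns after `K_true`'s traits.
#' @export
simulate_genetic_values <- function(G, K_true, seed) {
  G <- as.matrix(G)
  K_true <- as.matrix(K_true)
  set.seed(seed)
  LG <- matrix_sqrt(G)
  LK <- matrix_sqrt(K_true)
  n <- nrow(G)
  q <- nrow(K_true)
  E <- matrix(stats::rnorm(n * q), n, q)
  U <- LG %*% E %*% t(LK)
  rownames(U) <- rownames(G)
  colnames(U) <- colnames(K_true)
  U
}

#' Simulate plot-level multi-environment trial records
#'
#' Emits one record per (environment, replicate, line). Within each replicate
#' the lines are partitioned afresh into `n_blocks` incomplete blocks
#' (re-randomized per replicate, emulating the variance structure of an
#' alpha-lattice without reproducing its resolvability). The observation for
#' trait `t` is
#'
#' `mean_t + env + rep(env) + block(rep) + U[line, t] + ge + e_t`
#'
#' with all design effects IID normal at the configured variances (drawn
#' independently per trait), optional G x E deviations IID normal per
#' (line, env, trait), and residual rows drawn from `MVN(0, R_true)`.
#'
#' @param U n x q matrix of genetic values (rows = lines, columns = traits).
#' @param config A [sim_config()]; trait count must match `ncol(U)`.
#' @param seed RNG seed; defaults to `config$seed + 2L` so that genotype and
#'   trial streams differ under one configured seed.
#' @return A long-format `data.frame` (plot table) with columns
#'   `env, location, year, rep, block, genotype` and one column per trait.
#' @export
simulate_trial <- function(U, config, seed = config$seed + 2L) {
  config <- validate_sim_config(config)
  U <- as.matrix(U)
  q <- nrow(config$K_true)
  if (ncol(U) != q) {
    stop("`U` has ", ncol(U), " columns but `K_true` describes ", q,
         " traits", call. = FALSE)
  }
  if (nrow(U) != config$n_lines) {
    stop("`U` has ", nrow(U), " rows but config expects ", config$n_lines,
         " lines", call. = FALSE)
  }
  set.seed(seed)
  n <- config$n_lines
  lines <- rownames(U)
  if (is.null(lines)) lines <- sprintf("L%03d", seq_len(n))
  traits <- colnames(config$K_true)

  # location x year labels so the across-year adjustment is exercised:
  # two locations, years advancing every two environments
  loc <- paste0("LOC", ((seq_len(config$n_envs) - 1L) %% 2L) + 1L)
  year <- 2020L + (seq_len(config$n_envs) - 1L) %/% 2L
  envs <- paste0(loc, "_", year)

  sd0 <- function(v) if (v > 0) sqrt(v) else 0
  env_eff <- matrix(stats::rnorm(config$n_envs * q, 0, sd0(config$env_var)),
                    config$n_envs, q)
  rep_eff <- array(stats::rnorm(config$n_envs * config$n_reps * q, 0,
                                sd0(config$rep_var)),
                   c(config$n_envs, config$n_reps, q))
  blk_eff <- array(stats::rnorm(config$n_envs * config$n_reps *
                                  config$n_blocks * q, 0,
                                sd0(config$block_var)),
                   c(config$n_envs, config$n_reps, config$n_blocks, q))
  ge_eff <- array(if (config$ge_var > 0)
    stats::rnorm(n * config$n_envs * q, 0, sqrt(config$ge_var)) else 0,
    c(n, config$n_envs, q))
  LR <- matrix_sqrt(config$R_true)

  recs <- vector("list", config$n_envs * config$n_reps)
  k <- 0L
  for (e in seq_len(config$n_envs)) {
    for (r in seq_len(config$n_reps)) {
      blocks <- sample(rep_len(seq_len(config$n_blocks), n))
      eps <- matrix(stats::rnorm(n * q), n, q) %*% t(LR)
      vals <- matrix(rep(config$trait_means, each = n), n, q) +
        rep(env_eff[e, ], each = n) +
        rep(rep_eff[e, r, ], each = n) +
        matrix(blk_eff[e, r, blocks, ], n, q) +
        U + ge_eff[, e, ] + eps
      colnames(vals) <- traits
      k <- k + 1L
      recs[[k]] <- data.frame(env = envs[e], location = loc[e],
                              year = year[e],
                              rep = paste0("R", r),
                              block = paste0("B", blocks),
                              genotype = lines,
                              vals, check.names = FALSE,
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Write / read a plot table as long-format CSV
#'
#' @param plots Plot-table `data.frame` from [simulate_trial()] or equivalent.
#' @param path File path.
#' @return `read_plot_table` returns the plot-table `data.frame`.
#' @export
write_plot_table <- function(plots, path) {
  data.table::fwrite(plots, path)
  invisible(path)
}

#' @rdname write_plot_table
#' @export
read_plot_table <- function(path) {
  out <- as.data.frame(data.table::fread(path))
  needed <- c("env", "rep", "block", "genotype")
  miss <- setdiff(needed, names(out))
  if (length(miss)) {
    stop("plot table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  out
}
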