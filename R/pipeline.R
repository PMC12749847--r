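# End-to-end orchestration: simulate or ingest -> SNP QC + GRM -> design
# adjustment -> multi-trait fit -> CV2 comparison -> reports, under a single
# declarative configuration with one master seed.

#' Pipeline configuration
#'
#' Either `sim` (a [sim_config()] for fully synthetic runs) or both
#' `genotype_file` and `phenotype_file` must be supplied.
#'
#' @param sim Optional [sim_config()]; when present the pipeline simulates
#'   its own genotypes and trial data.
#' @param genotype_file,phenotype_file Paths to a dosage CSV/TSV (or `.vcf`)
#'   and a long-format plot CSV, used when `sim` is `NULL`.
#' @param traits Trait columns to analyze; default: all trait columns found.
#' @param maf_min,miss_max SNP QC thresholds (defaults 0.05 and 0.15).
#' @param mode Adjustment mode: `"within"`, `"across"` or `"across_year"`.
#' @param scenario Character vector naming the adjusted-means columns that
#'   form the multi-trait response (default: all columns).
#' @param cv_frac,cv_partitions CV2 testing fraction and partition count
#'   (defaults 0.30 and 100).
#' @param chain [mt_chain()] settings for the final multi-trait fit.
#' @param cv_chain [mt_chain()] settings for the per-partition fits.
#' @param seed Master seed; every stage seed is derived from it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = NULL, genotype_file = NULL,
                            phenotype_file = NULL, traits = NULL,
                            maf_min = 0.05, miss_max = 0.15,
                            mode = c("within", "across", "across_year"),
                            scenario = NULL,
                            cv_frac = 0.30, cv_partitions = 100L,
                            chain = mt_chain(),
                            cv_chain = mt_chain(n_iter = 1500L,
                                                burnin = 500L, thin = 2L),
                            seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(sim) && (is.null(genotype_file) || is.null(phenotype_file))) {
    stop("supply either `sim` or both `genotype_file` and `phenotype_file`",
         call. = FALSE)
  }
  structure(list(sim = sim, genotype_file = genotype_file,
                 phenotype_file = phenotype_file, traits = traits,
                 maf_min = maf_min, miss_max = miss_max, mode = mode,
                 scenario = scenario, cv_frac = cv_frac,
                 cv_partitions = as.integer(cv_partitions),
                 chain = chain, cv_chain = cv_chain,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; a `sim` block
#' is passed to [sim_config()] (via the same field names), and `chain` /
#' `cv_chain` blocks to [mt_chain()].
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$sim)) {
    for (m in c("K_true", "R_true")) {
      if (!is.null(raw$sim[[m]])) raw$sim[[m]] <- do.call(rbind, raw$sim[[m]])
    }
    if (!is.null(raw$sim$maf_range)) {
      raw$sim$maf_range <- unlist(raw$sim$maf_range)
    }
    if (is.null(raw$sim$seed) && !is.null(raw$seed)) raw$sim$seed <- raw$seed
    raw$sim <- do.call(sim_config, raw$sim)
  }
  for (ch in c("chain", "cv_chain")) {
    if (!is.null(raw[[ch]])) raw[[ch]] <- do.call(mt_chain, raw[[ch]])
  }
  do.call(pipeline_config, raw)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full genomic-selection pipeline
#'
#' Stages: (1) obtain genotypes (simulate or read); (2) SNP QC, imputation
#' and GRM construction; (3) obtain plot-level phenotypes (simulate the
#' trial from genetic values drawn against the realized GRM, or read);
#' (4) design adjustment to line x column adjusted means, complete-case
#' filtered and aligned with the GRM; (5) multi-trait fit on the scenario
#' columns and the heritability/correlation summary matrix; (6) CV2
#' comparison of single- vs multi-trait prediction accuracy. All stage
#' outputs are written as labeled CSV/JSON under `out_dir` together with a
#' machine-readable manifest, and the run is deterministic given the
#' configured seed.
#'
#' @param config A [pipeline_config()] (or path to a YAML file for
#'   [read_pipeline_config()]).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory artifacts: `qc`, `G`,
#'   `adjusted` (means + variance components), `Y` (filtered response
#'   matrix), `mt_fit`, `summary_matrix`, `pa` and `gain`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  timings <- list()
  tick <- function(name, t_start) {
    timings[[name]] <<- round(as.numeric(Sys.time()) - as.numeric(t_start), 3)
  }

  # (1) genotypes
  ts <- Sys.time()
  gm <- stage("genotypes", {
    if (!is.null(config$sim)) {
      simulate_genotypes(config$sim, seed = config$seed)
    } else if (grepl("\\.vcf(\\.gz)?$", config$genotype_file)) {
      read_genotypes_vcf(config$genotype_file)
    } else {
      read_genotypes(config$genotype_file)
    }
  })
  tick("genotypes", ts)

  # (2) QC + GRM
  ts <- Sys.time()
  qc <- stage("qc", filter_snps(gm, config$maf_min, config$miss_max))
  X <- stage("impute", impute_mean(qc$genotypes))
  G <- stage("grm", build_grm(X))
  write_qc_report(qc$report, file.path(out_dir, "qc_report.csv"))
  write_grm(G, file.path(out_dir, "grm.csv"))
  tick("qc_grm", ts)

  # (3) phenotypes
  ts <- Sys.time()
  if (!is.null(config$sim)) {
    U <- stage("genetic_values",
               simulate_genetic_values(G, config$sim$K_true,
                                       seed = config$seed + 1L))
    plots <- stage("trial",
                   simulate_trial(U, config$sim, seed = config$seed + 2L))
  } else {
    plots <- stage("phenotypes", read_plot_table(config$phenotype_file))
  }
  trait_cols <- config$traits
  if (is.null(trait_cols)) {
    trait_cols <- setdiff(names(plots),
                          c("env", "location", "year", "rep", "block",
                            "genotype"))
  }
  missing_tr <- setdiff(trait_cols, names(plots))
  if (length(missing_tr)) {
    stop("pipeline stage 'phenotypes' failed: trait column(s) not in data: ",
         paste(missing_tr, collapse = ", "), call. = FALSE)
  }
  write_plot_table(plots, file.path(out_dir, "plot_table.csv"))
  tick("phenotypes", ts)

  # (4) adjustment
  ts <- Sys.time()
  adj <- stage("adjustment", adjust_means(plots, trait_cols, config$mode))
  scen <- config$scenario
  if (is.null(scen)) scen <- colnames(adj$means)
  absent <- setdiff(scen, colnames(adj$means))
  if (length(absent)) {
    stop("pipeline stage 'scenario' failed: column(s) not produced by the ",
         "adjustment: ", paste(absent, collapse = ", "),
         "; available: ", paste(colnames(adj$means), collapse = ", "),
         call. = FALSE)
  }
  Y <- stage("complete_cases",
             complete_case_filter(adj$means[, scen, drop = FALSE]))
  keep <- intersect(rownames(Y), rownames(G))
  if (length(keep) < 2L) {
    stop("pipeline stage 'alignment' failed: fewer than two lines carry ",
         "both marker and phenotype data", call. = FALSE)
  }
  Y <- Y[keep, , drop = FALSE]
  Gk <- G[keep, keep, drop = FALSE]
  utils::write.csv(data.frame(line_id = rownames(adj$means), adj$means,
                              check.names = FALSE),
                   file.path(out_dir, "adjusted_means.csv"),
                   row.names = FALSE)
  jsonlite::write_json(adj$varcomp,
                       file.path(out_dir, "variance_components.json"),
                       auto_unbox = TRUE, digits = NA)
  tick("adjustment", ts)

  # (5) multi-trait fit + summary matrix
  ts <- Sys.time()
  mt_fit <- NULL
  smat <- NULL
  if (ncol(Y) >= 2L) {
    mt_fit <- stage("mt_fit",
                    fit_mt_gblup(Y, Gk, chain = config$chain,
                                 seed = config$seed + 3L))
    smat <- build_summary_matrix(mt_fit)
    utils::write.csv(format_summary_matrix(smat),
                     file.path(out_dir, "summary_matrix.csv"))
    write_mt_fit(mt_fit, file.path(out_dir, "mt_fit.json"))
  }
  tick("mt_fit", ts)

  # (6) CV2 comparison
  ts <- Sys.time()
  parts <- stage("cv2_partitions",
                 make_cv2_partitions(rownames(Y), q = ncol(Y),
                                     frac = config$cv_frac,
                                     n_partitions = config$cv_partitions,
                                     seed = config$seed + 4L))
  pa <- stage("cv2", run_comparison(Y, Gk, parts, chain = config$cv_chain,
                                    mt_seed = config$seed + 5L))
  gain <- summarize_gain(pa)
  utils::write.csv(gain, file.path(out_dir, "pa_summary.csv"),
                   row.names = FALSE)
  write_cv2_partitions(parts, file.path(out_dir, "cv2_partitions.csv"))
  tick("cv2", ts)

  manifest <- list(
    package_version = as.character(utils::packageVersion("mtgblup")),
    r_version = R.version.string,
    seed = config$seed,
    stage_seeds = list(genotypes = config$seed,
                       genetic_values = config$seed + 1L,
                       trial = config$seed + 2L,
                       mt_fit = config$seed + 3L,
                       cv2_partitions = config$seed + 4L,
                       cv2_chains = config$seed + 5L),
    n_lines = nrow(Y), columns = colnames(Y),
    n_snps_kept = sum(qc$report$kept),
    mode = config$mode,
    cv = list(frac = config$cv_frac, n_partitions = config$cv_partitions,
              m = parts$m, n_tst_j = parts$n_tst_j, n_tst = parts$n_tst,
              n_trn_j = parts$n_trn_j, n_trn = parts$n_trn),
    timings_sec = timings,
    total_sec = round(as.numeric(Sys.time()) - as.numeric(t0), 3))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(qc = qc, G = G, adjusted = adj, Y = Y, mt_fit = mt_fit,
                 summary_matrix = smat, partitions = parts, pa = pa,
                 gain = gain, manifest = manifest))
}

#' Three-zone trait summary matrix
#'
#' Assembles the publication-style q x q display in which heritabilities sit
#' on the diagonal, genetic correlations below it and genetic covariances
#' above it, each accompanied by its posterior standard deviation.
#'
#' @param fit An [fit_mt_gblup()] result with at least two columns.
#' @return Object of class `summary_matrix`: list with `estimate` and `sd`
#'   matrices plus the zone legend.
#' @export
build_summary_matrix <- function(fit) {
  stopifnot(inherits(fit, "mt_gblup"))
  q <- ncol(fit$K)
  if (q < 2L) stop("the summary matrix needs at least two columns",
                   call. = FALSE)
  est <- matrix(NA_real_, q, q, dimnames = dimnames(fit$K))
  sdm <- est
  diag(est) <- fit$h2
  diag(sdm) <- fit$h2_sd
  for (a in 1:(q - 1)) for (b in (a + 1):q) {
    est[a, b] <- fit$K[a, b]       # covariance above the diagonal
    sdm[a, b] <- fit$K_sd[a, b]
    est[b, a] <- fit$rg[a, b]      # correlation below the diagonal
    sdm[b, a] <- fit$rg_sd[a, b]
  }
  structure(list(estimate = est, sd = sdm,
                 legend = paste("diagonal: heritability;",
                                "below: genetic correlation;",
                                "above: genetic covariance")),
            class = "summary_matrix")
}

format_summary_matrix <- function(x) {
  q <- nrow(x$estimate)
  out <- matrix(sprintf("%.3f (%.3f)", x$estimate, x$sd), q, q,
                dimnames = dimnames(x$estimate))
  as.data.frame(out)
}

#' @export
print.summary_matrix <- function(x, ...) {
  cat("trait summary matrix (", x$legend, ")\n", sep = "")
  print(format_summary_matrix(x))
  invisible(x)
}

#' Serialize / restore a multi-trait fit as JSON
#'
#' Stores posterior summaries (not the sample chains) with row-major
#' matrices and labels; `read_mt_fit` restores an `mt_gblup` object
#' sufficient to rebuild reports.
#'
#' @param fit An `mt_gblup` object.
#' @param path JSON file path.
#' @return `read_mt_fit` returns the restored `mt_gblup` object.
#' @export
write_mt_fit <- function(fit, path) {
  payload <- list(traits = colnames(fit$K),
                  K = fit$K, K_sd = fit$K_sd, R = fit$R, R_sd = fit$R_sd,
                  mu = as.list(fit$mu), h2 = as.list(fit$h2),
                  h2_sd = as.list(fit$h2_sd),
                  rg = fit$rg, rg_sd = fit$rg_sd,
                  n_saved = fit$n_saved,
                  chain = unclass(fit$chain), seed = fit$seed)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_mt_fit
#' @export
read_mt_fit <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  traits <- p$traits
  fix <- function(M) {
    M <- as.matrix(M)
    dimnames(M) <- list(traits, traits)
    M
  }
  structure(list(K = fix(p$K), K_sd = fix(p$K_sd), R = fix(p$R),
                 R_sd = fix(p$R_sd),
                 mu = unlist(p$mu), h2 = unlist(p$h2),
                 h2_sd = unlist(p$h2_sd),
                 rg = fix(p$rg), rg_sd = fix(p$rg_sd),
                 predictions = NULL, predictions_sd = NULL,
                 h2_samples = NULL, rg_samples = NULL,
                 n_saved = p$n_saved,
                 chain = do.call(mt_chain, p$chain), seed = p$seed),
            class = "mt_gblup")
}
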