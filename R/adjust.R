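# Design adjustment of plot-level trial data: genotype fixed, all design
# terms random IID normal, variance components by REML (lme4), genotype
# least-squares means (BLUEs) as the adjusted phenotype.

required_plot_cols <- function(plots, trait) {
  needed <- c("env", "rep", "block", "genotype", trait)
  miss <- setdiff(needed, names(plots))
  if (length(miss)) {
    stop("plot table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  invisible(plots)
}

# Build an lmer formula keeping only random terms whose grouping factor has
# >= 2 levels on this data (a one-level grouping factor is unidentifiable and
# its variance is reported as 0).
build_adjust_formula <- function(dat, trait, terms) {
  keep <- vapply(terms, function(tm) {
    cols <- strsplit(tm, ":", fixed = TRUE)[[1]]
    grp <- do.call(interaction, c(unname(as.list(dat[cols])), drop = TRUE))
    nlevels(grp) >= 2L
  }, logical(1))
  rand <- terms[keep]
  rhs <- "0 + genotype"
  if (length(rand)) {
    rhs <- paste(rhs, paste(sprintf("(1 | %s)", rand), collapse = " + "),
                 sep = " + ")
  }
  list(formula = stats::as.formula(paste0("`", trait, "` ~ ", rhs)),
       dropped = terms[!keep], random = rand)
}

extract_varcomp <- function(fit, terms) {
  vc <- as.data.frame(lme4::VarCorr(fit))
  out <- stats::setNames(rep(0, length(terms) + 1L), c(terms, "residual"))
  for (i in seq_len(nrow(vc))) {
    g <- vc$grp[i]
    if (g == "Residual") out["residual"] <- vc$vcov[i]
    else if (g %in% terms) out[g] <- vc$vcov[i]
  }
  out
}

ls_means_from_fit <- function(fit, all_genos) {
  fe <- lme4::fixef(fit)
  names(fe) <- sub("^genotype", "", names(fe))
  means <- stats::setNames(rep(NA_real_, length(all_genos)), all_genos)
  means[names(fe)] <- fe
  means
}

#' Within-environment design adjustment
#'
#' Fits, for one trait in one environment, the model
#' `y = mu + Rep + Block:Rep + Gen + error` with genotype fixed and
#' replicate and block-within-replicate random IID normal (REML). The
#' genotype least-squares means (BLUEs, random effects integrated out) are
#' returned as the adjusted phenotype.
#'
#' @param plots Plot-level `data.frame` with columns
#'   `env, rep, block, genotype` and the trait.
#' @param trait Trait column name.
#' @param env Environment id to subset on.
#' @return A list of class `env_adjustment`: `means` (named vector over all
#'   genotypes present anywhere in `plots`; `NA` where a genotype was absent
#'   from this environment), `varcomp` (named vector: `rep`, `rep:block`,
#'   `residual`), `env`, `trait`, and `fit` (the `lmerMod`/`lm` object).
#' @export
fit_within_env <- function(plots, trait, env) {
  required_plot_cols(plots, trait)
  all_genos <- sort(unique(as.character(plots$genotype)))
  dat <- plots[plots$env == env & !is.na(plots[[trait]]), , drop = FALSE]
  if (length(unique(dat$genotype)) < 2L) {
    stop("fewer than two genotypes observed in environment ", env,
         call. = FALSE)
  }
  dat$genotype <- factor(as.character(dat$genotype))
  dat$rep <- factor(as.character(dat$rep))
  dat$block <- factor(as.character(dat$block))
  bf <- build_adjust_formula(dat, trait, c("rep", "rep:block"))
  fit <- fit_adjustment_model(bf, dat, trait)
  means <- ls_means_from_fit(fit$fit, all_genos)
  structure(list(means = means,
                 varcomp = extract_varcomp_safe(fit, c("rep", "rep:block")),
                 env = env, trait = trait, fit = fit$fit),
            class = "env_adjustment")
}

# Fit lmer, falling back to plain fixed-effects lm when no random term
# survives (e.g. single replicate with one block).
fit_adjustment_model <- function(bf, dat, trait) {
  if (length(bf$random) == 0L) {
    f <- stats::as.formula(paste0("`", trait, "` ~ 0 + genotype"))
    return(list(fit = stats::lm(f, data = dat), lmer = FALSE))
  }
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(bf$formula, data = dat, REML = TRUE,
               control = lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                                           check.nobs.vs.nRE = "ignore"))))
  list(fit = fit, lmer = TRUE)
}

extract_varcomp_safe <- function(fit, terms) {
  if (isTRUE(fit$lmer)) return(extract_varcomp(fit$fit, terms))
  out <- stats::setNames(rep(0, length(terms) + 1L), c(terms, "residual"))
  out["residual"] <- summary(fit$fit)$sigma^2
  out
}

#' Across-environment design adjustment
#'
#' Fits `y = mu + Env + Rep:Env + Block:Rep:Env + Gen + Gen:Env + error`
#' with genotype fixed and every other term random IID normal (REML);
#' environments are location x year combinations. With
#' `env_factor = "year"` the environment term is replaced by the year,
#' giving the within-location across-year adjustment used when one location
#' is analyzed over several seasons.
#'
#' @param plots Plot-level `data.frame`; must carry a `year` column when
#'   `env_factor = "year"`.
#' @param trait Trait column name.
#' @param env_factor `"environment"` (default) or `"year"`.
#' @return A list of class `env_adjustment` with `means`, `varcomp` (named
#'   `env`, `env:rep`, `env:rep:block`, `genotype:env`, `residual`),
#'   `connected` (FALSE when genotype sets of the environment levels are
#'   disjoint, which makes genotype comparisons rely on the random-effect
#'   assumptions only), and the fitted model.
#' @export
fit_across_env <- function(plots, trait, env_factor = c("environment", "year")) {
  env_factor <- match.arg(env_factor)
  required_plot_cols(plots, trait)
  all_genos <- sort(unique(as.character(plots$genotype)))
  dat <- plots[!is.na(plots[[trait]]), , drop = FALSE]
  dat$envf <- factor(as.character(
    if (env_factor == "year") dat$year else dat$env))
  if (nlevels(dat$envf) < 2L) {
    stop("only one level of the environment factor; use fit_within_env()",
         call. = FALSE)
  }
  dat$genotype <- factor(as.character(dat$genotype))
  dat$rep <- factor(as.character(dat$rep))
  dat$block <- factor(as.character(dat$block))
  connected <- design_connected(dat$genotype, dat$envf)
  if (!connected) {
    warning("genotype sets are unconnected across environment levels; ",
            "adjusted means are only comparable through the random-effect ",
            "assumptions", call. = FALSE)
  }
  terms <- c("envf", "envf:rep", "envf:rep:block", "genotype:envf")
  bf <- build_adjust_formula(dat, trait, terms)
  fit <- fit_adjustment_model(bf, dat, trait)
  vc <- extract_varcomp_safe(fit, terms)
  names(vc) <- sub("^envf", "env", gsub(":envf", ":env", names(vc)))
  names(vc)[names(vc) == "env:rep:block"] <- "env:rep:block"
  means <- ls_means_from_fit(fit$fit, all_genos)
  structure(list(means = means, varcomp = vc, env = "across",
                 trait = trait, env_factor = env_factor,
                 connected = connected, fit = fit$fit),
            class = "env_adjustment")
}

# Environments are connected when the bipartite genotype-environment graph
# has a single connected component among environments.
design_connected <- function(genotype, envf) {
  envs <- levels(envf)
  if (length(envs) < 2L) return(TRUE)
  sets <- lapply(envs, function(e) unique(genotype[envf == e]))
  comp <- seq_along(envs)
  repeat {
    changed <- FALSE
    for (i in seq_along(envs)) for (j in seq_along(envs)) {
      if (comp[i] != comp[j] && length(intersect(sets[[i]], sets[[j]]))) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  length(unique(comp)) == 1L
}

#' Assemble the adjusted-means matrix over traits (and environments)
#'
#' Runs the design adjustment for each trait (and, in `"within"` mode, each
#' environment) and assembles the lines x columns adjusted-phenotype matrix
#' used as the response for genomic prediction. Column labels are
#' `<trait>_<env>` in within mode and `<trait>` otherwise.
#'
#' @param plots Plot-level `data.frame`.
#' @param traits Character vector of trait column names.
#' @param mode `"within"` (per-environment), `"across"` (across
#'   environments) or `"across_year"` (across years within a location).
#' @return A list with `means` (numeric matrix, possibly containing `NA`
#'   before [complete_case_filter()]) and `varcomp` (named list of
#'   variance-component vectors per column).
#' @export
adjust_means <- function(plots, traits, mode = c("within", "across",
                                                 "across_year")) {
  mode <- match.arg(mode)
  cols <- list()
  vcs <- list()
  if (mode == "within") {
    for (tr in traits) for (e in unique(as.character(plots$env))) {
      a <- fit_within_env(plots, tr, e)
      lab <- paste0(tr, "_", e)
      cols[[lab]] <- a$means
      vcs[[lab]] <- a$varcomp
    }
  } else {
    for (tr in traits) {
      a <- fit_across_env(plots, tr,
                          if (mode == "across_year") "year" else "environment")
      cols[[tr]] <- a$means
      vcs[[tr]] <- a$varcomp
    }
  }
  genos <- sort(unique(as.character(plots$genotype)))
  M <- do.call(cbind, lapply(cols, function(m) m[genos]))
  rownames(M) <- genos
  list(means = M, varcomp = vcs)
}

#' Drop lines with any missing adjusted mean
#'
#' Complete-case filtering of the adjusted-means matrix: every line with at
#' least one missing column is excluded, preserving line order.
#'
#' @param means Lines x columns numeric matrix (may contain `NA`).
#' @return The filtered matrix.
#' @export
complete_case_filter <- function(means) {
  means <- as.matrix(means)
  keep <- stats::complete.cases(means)
  if (!any(keep)) stop("no line has complete data across all columns",
                       call. = FALSE)
  means[keep, , drop = FALSE]
}
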