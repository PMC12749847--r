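# CV2 cross-validation: lines are masked in pairs of columns
# (trait-environment combinations) so that multi-trait models can borrow
# same-line information from the columns left observed, and single- and
# multi-trait models are compared on identical folds.

#' Generate pair-balanced CV2 partitions
#'
#' For each partition, `m = floor(ceil(frac * n) / (q - 1))` lines are
#' assigned to each of the `choose(q, 2)` unordered column pairs (every
#' sampled line appears in exactly one pair and is masked in exactly the two
#' columns of that pair), so all pairs are equally represented and each
#' column ends up with `n_tst_j = m * (q - 1)` testing cells, about
#' `frac * n` of its lines. With `q = 2` there is a single pair and each
#' sampled line is masked in both columns. One child seed per partition is
#' drawn from the master seed, so partitions are reproducible individually
#' and identical masks are reused for the single- and multi-trait fits.
#'
#' @param line_ids Character vector of line identifiers (length n).
#' @param q Number of response columns (>= 2).
#' @param frac Target within-column testing fraction (default 0.30).
#' @param n_partitions Number of independent partitions (default 100).
#' @param seed Master RNG seed.
#' @return Object of class `cv2_partition_set`: a list with `partitions`
#'   (each of class `cv2_partition` carrying `index`, `assignment`
#'   (line, col_a, col_b), `mask` (n x q logical) and `test_cells`),
#'   plus `m`, `n_tst_j`, `n_tst`, `n_trn_j`, `n_trn`, `q`, `frac`, `seed`.
#' @export
make_cv2_partitions <- function(line_ids, q, frac = 0.30,
                                n_partitions = 100L, seed = 1L) {
  line_ids <- as.character(line_ids)
  n <- length(line_ids)
  if (q < 2L) stop("CV2 needs at least two columns", call. = FALSE)
  if (frac <= 0 || frac >= 1) stop("`frac` must lie in (0, 1)", call. = FALSE)
  m <- floor(ceiling(frac * n) / (q - 1))
  if (m < 1L) stop("infeasible testing fraction: no complete pair fits",
                   call. = FALSE)
  pairs <- utils::combn(q, 2L)
  n_pairs <- ncol(pairs)
  if (m * n_pairs > n) {
    stop("infeasible design: ", m, " lines per pair x ", n_pairs,
         " pairs exceeds ", n, " lines", call. = FALSE)
  }
  set.seed(seed)
  child_seeds <- sample.int(.Machine$integer.max, n_partitions)
  parts <- vector("list", n_partitions)
  for (p in seq_len(n_partitions)) {
    set.seed(child_seeds[p])
    sampled <- sample(line_ids, m * n_pairs)
    pair_of <- rep(seq_len(n_pairs), each = m)
    assignment <- data.frame(line = sampled,
                             col_a = pairs[1L, pair_of],
                             col_b = pairs[2L, pair_of],
                             stringsAsFactors = FALSE)
    mask <- matrix(FALSE, n, q, dimnames = list(line_ids, NULL))
    ri <- match(sampled, line_ids)
    mask[cbind(ri, assignment$col_a)] <- TRUE
    mask[cbind(ri, assignment$col_b)] <- TRUE
    cells <- which(mask, arr.ind = TRUE)
    parts[[p]] <- structure(
      list(index = p,
           assignment = assignment,
           mask = mask,
           test_cells = data.frame(line = line_ids[cells[, 1L]],
                                   col = cells[, 2L],
                                   stringsAsFactors = FALSE),
           seed = child_seeds[p]),
      class = "cv2_partition")
  }
  structure(list(partitions = parts, line_ids = line_ids,
                 m = m, q = q, frac = frac,
                 n_tst_j = m * (q - 1L), n_tst = m * (q - 1L) * q,
                 n_trn_j = n - m * (q - 1L),
                 n_trn = (n - m * (q - 1L)) * q,
                 n_partitions = n_partitions, seed = seed),
            class = "cv2_partition_set")
}

#' @export
print.cv2_partition_set <- function(x, ...) {
  cat(sprintf(
    "cv2_partition_set: %d partitions, n = %d lines, q = %d columns\n",
    x$n_partitions, length(x$line_ids), x$q))
  cat(sprintf("m = %d lines/pair; n_tst_j = %d, n_tst = %d; n_trn_j = %d, n_trn = %d\n",
              x$m, x$n_tst_j, x$n_tst, x$n_trn_j, x$n_trn))
  invisible(x)
}

#' Serialize CV2 partitions to a long CSV
#'
#' One row per masked (partition, line, column) cell.
#' @param partitions A `cv2_partition_set`.
#' @param path File path.
#' @export
write_cv2_partitions <- function(partitions, path) {
  rows <- lapply(partitions$partitions, function(p) {
    data.frame(partition = p$index, p$test_cells, role = "testing",
               stringsAsFactors = FALSE)
  })
  data.table::fwrite(do.call(rbind, rows), path, quote = FALSE)
  invisible(path)
}

safe_cor <- function(a, b) {
  if (length(a) < 3L) return(NA_real_)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

#' Run the ST vs MT prediction-accuracy comparison on shared CV2 folds
#'
#' For every partition: the single-trait model is fitted per column on that
#' column's unmasked lines and predicts its masked lines; the multi-trait
#' model is fitted once on all unmasked cells jointly (Gibbs sampler with
#' the masked cells treated as missing) and its posterior-mean predictions
#' are read off at the masked cells. Prediction accuracy is the Pearson
#' correlation between observed and predicted values per column; partitions
#' where a column's correlation is undefined (fewer than 3 cells or zero
#' variance) are recorded as `NA`, counted, and excluded from averages.
#'
#' @param Y Complete (no `NA`) n x q adjusted-means matrix, rows aligned
#'   with `G` and with `partitions$line_ids`.
#' @param G Relationship matrix.
#' @param partitions A [make_cv2_partitions()] result.
#' @param chain [mt_chain()] settings for the multi-trait fits; cross-
#'   validation runs typically use shorter chains than a final fit.
#' @param mt_seed Base seed for the per-partition sampler chains.
#' @param verbose Print a progress line per partition.
#' @return Object of class `pa_summary`; see [pa_summary()].
#' @export
run_comparison <- function(Y, G, partitions,
                           chain = mt_chain(n_iter = 1500L, burnin = 500L,
                                            thin = 2L),
                           mt_seed = 1L, verbose = FALSE) {
  Y <- as.matrix(Y)
  if (anyNA(Y)) stop("`Y` must be complete-case filtered first", call. = FALSE)
  if (!identical(rownames(Y), partitions$line_ids)) {
    stop("rows of `Y` must match the partition line ids", call. = FALSE)
  }
  if (!identical(rownames(Y), rownames(G))) {
    stop("rows of `Y` and `G` must match", call. = FALSE)
  }
  q <- ncol(Y)
  if (q != partitions$q) {
    stop("partitions were generated for q = ", partitions$q,
         " columns but `Y` has ", q, call. = FALSE)
  }
  np <- partitions$n_partitions
  pa_st <- matrix(NA_real_, np, q)
  pa_mt <- matrix(NA_real_, np, q)
  cols <- colnames(Y)
  if (is.null(cols)) cols <- paste0("C", seq_len(q))
  colnames(pa_st) <- colnames(pa_mt) <- cols

  for (p in seq_len(np)) {
    part <- partitions$partitions[[p]]
    mask <- part$mask
    # single-trait: per column, train on unmasked lines of that column
    for (j in seq_len(q)) {
      trn <- rownames(Y)[!mask[, j]]
      tst <- rownames(Y)[mask[, j]]
      if (!length(tst)) next
      pred <- predict_st(Y[, j], G, trn, tst)
      pa_st[p, j] <- safe_cor(Y[tst, j], as.numeric(pred))
    }
    # multi-trait: one joint fit with masked cells hidden
    Ymask <- Y
    Ymask[mask] <- NA_real_
    fit <- fit_mt_gblup(Ymask, G, chain = chain, seed = mt_seed + p)
    for (j in seq_len(q)) {
      tst <- rownames(Y)[mask[, j]]
      if (!length(tst)) next
      pa_mt[p, j] <- safe_cor(Y[tst, j], fit$predictions[tst, j])
    }
    if (verbose) {
      message(sprintf("partition %d/%d: mean PA st = %.3f, mt = %.3f",
                      p, np, mean(pa_st[p, ], na.rm = TRUE),
                      mean(pa_mt[p, ], na.rm = TRUE)))
    }
  }
  pa_summary(pa_st, pa_mt)
}

#' Prediction-accuracy summary container
#'
#' Holds the per-partition, per-column Pearson accuracies of the single- and
#' multi-trait models evaluated on identical folds, plus the number of
#' partitions where a correlation was undefined.
#'
#' @param pa_st,pa_mt Partitions x columns numeric matrices of accuracies
#'   (`NA` for undefined correlations), identical dimensions.
#' @return Object of class `pa_summary`.
#' @export
pa_summary <- function(pa_st, pa_mt) {
  pa_st <- as.matrix(pa_st)
  pa_mt <- as.matrix(pa_mt)
  if (!identical(dim(pa_st), dim(pa_mt))) {
    stop("accuracy matrices must share dimensions (identical partitions)",
         call. = FALSE)
  }
  structure(list(pa_st = pa_st, pa_mt = pa_mt,
                 n_undefined = colSums(is.na(pa_st) | is.na(pa_mt))),
            class = "pa_summary")
}

#' Per-column accuracy gain and Pr of the multi-trait model
#'
#' `gain = mean PA(MT) - mean PA(ST)` per column; `Pr` is the fraction of
#' partitions in which the multi-trait accuracy strictly exceeds the
#' single-trait accuracy (ties count against the multi-trait model).
#'
#' @param summary A [pa_summary()] object.
#' @return A `data.frame` with one row per column: `column, mean_pa_st,
#'   sd_pa_st, mean_pa_mt, sd_pa_mt, gain, pr, n_partitions, n_undefined`.
#' @export
summarize_gain <- function(summary) {
  stopifnot(inherits(summary, "pa_summary"))
  st <- summary$pa_st
  mt <- summary$pa_mt
  cols <- colnames(st)
  if (is.null(cols)) cols <- paste0("C", seq_len(ncol(st)))
  both <- !is.na(st) & !is.na(mt)
  data.frame(
    column = cols,
    mean_pa_st = colMeans(st, na.rm = TRUE),
    sd_pa_st = apply(st, 2, stats::sd, na.rm = TRUE),
    mean_pa_mt = colMeans(mt, na.rm = TRUE),
    sd_pa_mt = apply(mt, 2, stats::sd, na.rm = TRUE),
    gain = colMeans(mt, na.rm = TRUE) - colMeans(st, na.rm = TRUE),
    pr = vapply(seq_along(cols), function(j) {
      b <- both[, j]
      if (!any(b)) return(NA_real_)
      mean(mt[b, j] > st[b, j])
    }, numeric(1)),
    n_partitions = nrow(st),
    n_undefined = summary$n_undefined,
    row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.pa_summary <- function(x, ...) {
  print(summarize_gain(x), digits = 3)
  invisible(x)
}
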