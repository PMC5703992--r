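# Exhaustive enumeration and evaluation of all small logistic-regression
# classifiers under leave-one-out cross-validation.

#' Number of feature combinations searched
#'
#' Count of nonempty feature subsets of size at most `max_k` from a pool:
#' `sum(choose(pool_size, 1:max_k))`. The intercept-only (empty) model is
#' not counted by default; `include_empty = TRUE` adds one.
#'
#' @param pool_size Number of candidate features.
#' @param max_k Maximum features per classifier (default 5).
#' @param include_empty Count the intercept-only model too?
#' @return Integer-valued count.
#' @export
#' @examples
#' combination_count(11)  # 1023
#' combination_count(27)  # 101583
combination_count <- function(pool_size, max_k = 5, include_empty = FALSE) {
  stopifnot(pool_size >= 1, max_k >= 1)
  sum(choose(pool_size, seq_len(min(max_k, pool_size)))) + include_empty
}

#' Enumerate feature combinations
#'
#' Deterministically enumerates every nonempty subset of `1:pool_size` with
#' at most `max_k` elements, ordered by subset size and lexicographically
#' within each size. Any execution order over combinations must yield
#' identical results (they are independent); this fixed order makes runs
#' reproducible.
#'
#' @inheritParams combination_count
#' @return List of integer index vectors.
#' @export
#' @examples
#' length(enumerate_combinations(5))  # 31
enumerate_combinations <- function(pool_size, max_k = 5) {
  stopifnot(pool_size >= 1, max_k >= 1)
  out <- vector("list", combination_count(pool_size, max_k))
  pos <- 0L
  for (k in seq_len(min(max_k, pool_size))) {
    cmb <- utils::combn(pool_size, k)
    for (j in seq_len(ncol(cmb))) {
      pos <- pos + 1L
      out[[pos]] <- cmb[, j]
    }
  }
  out
}

#' Exhaustively search small logistic-regression classifiers
#'
#' Fits one logistic-regression classifier per combination of up to
#' `max_features` features from the pool (the cap limits the
#' feature-to-case ratio). Each combination gets a full-data fit (for
#' multivariate odds ratios and Wald P-values, in original feature units)
#' and a leave-one-out cross-validated score vector, summarized by ROC
#' AUC. Results are ranked by AUC (descending), ties broken by fewer
#' features then lexicographic feature names.
#'
#' @param x Numeric feature matrix (patients x features) with column names
#'   and patient-id rownames; raw units, not the standardized matrix used
#'   for subset selection.
#' @param y Binary outcome vector aligned with the rows of `x`.
#' @param pool Character vector of candidate feature names (typically the
#'   `chosen_features` of [select_feature_subset()]); defaults to all
#'   columns.
#' @param max_features Maximum features per classifier (default 5).
#' @param top_n Number of top-ranked classifiers whose LOOCV score vectors
#'   are retained in the result (default 100).
#' @param ridge_lambda Separation fallback penalty, see [fit_logistic()].
#' @return An object of class `task_result`: \describe{
#'   \item{results}{data.frame, one row per combination (rank order):
#'     `combo_id`, `n_features`, `features` (`+`-separated names), `auc`,
#'     `converged`, `ridge_fallback`.}
#'   \item{coef_table}{data.frame of per-feature full-fit statistics for
#'     every combination: `combo_id`, `feature`, `coef`, `odds_ratio`,
#'     `or_lower`, `or_upper`, `p_value`.}
#'   \item{top_scores}{matrix (patients x top combinations) of LOOCV
#'     probabilities, columns named by `combo_id`.}
#'   \item{labels}{the outcome vector, named by patient id.}
#' }
#' @export
run_task <- function(x, y, pool = colnames(x), max_features = 5,
                     top_n = 100, ridge_lambda = 1e-6) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  stopifnot(nrow(x) == length(y), all(y %in% c(0, 1)))
  if (length(unique(y)) < 2L) {
    stop("labels contain a single class; nothing to predict", call. = FALSE)
  }
  missing_pool <- setdiff(pool, colnames(x))
  if (length(missing_pool)) {
    stop("pool feature(s) not in matrix: ",
         paste(missing_pool, collapse = ", "), call. = FALSE)
  }
  x <- x[, pool, drop = FALSE]
  n <- nrow(x)
  combos <- enumerate_combinations(length(pool), max_features)
  nc <- length(combos)

  auc_v <- numeric(nc)
  conv_v <- logical(nc)
  ridge_v <- logical(nc)
  feat_v <- character(nc)
  k_v <- integer(nc)
  scores_m <- matrix(NA_real_, n, nc)
  coef_rows <- vector("list", nc)
  y_cases <- y == 1

  for (ci in seq_len(nc)) {
    idx <- combos[[ci]]
    xs <- x[, idx, drop = FALSE]
    full <- fit_logistic(xs, y, ridge_lambda = ridge_lambda)
    sc <- loocv_scores(xs, y, ridge_lambda = ridge_lambda,
                       start = full$coefficients)
    auc_v[ci] <- .auc_fast(sc, y_cases)
    conv_v[ci] <- full$converged
    ridge_v[ci] <- full$ridge_fallback
    k_v[ci] <- length(idx)
    feat_v[ci] <- paste(pool[idx], collapse = "+")
    scores_m[, ci] <- sc
    fnames <- pool[idx]
    coef_rows[[ci]] <- data.frame(
      combo_id = ci, feature = fnames,
      coef = unname(full$coefficients[fnames]),
      odds_ratio = unname(full$odds_ratio[fnames]),
      or_lower = unname(full$or_ci[fnames, "lower"]),
      or_upper = unname(full$or_ci[fnames, "upper"]),
      p_value = unname(full$p_value[fnames]),
      stringsAsFactors = FALSE)
  }

  ord <- order(-auc_v, k_v, feat_v)
  results <- data.frame(combo_id = ord, n_features = k_v[ord],
                        features = feat_v[ord], auc = auc_v[ord],
                        converged = conv_v[ord],
                        ridge_fallback = ridge_v[ord],
                        stringsAsFactors = FALSE, row.names = NULL)
  keep <- ord[seq_len(min(top_n, nc))]
  top_scores <- scores_m[, keep, drop = FALSE]
  dimnames(top_scores) <- list(rownames(x), as.character(keep))

  structure(list(pool = pool, max_features = max_features,
                 results = results,
                 coef_table = do.call(rbind, coef_rows),
                 top_scores = top_scores,
                 labels = stats::setNames(y, rownames(x))),
            class = "task_result")
}

#' @export
print.task_result <- function(x, ...) {
  cat(sprintf(
    "<task_result> %d classifiers over %d features (max %d per model)\n",
    nrow(x$results), length(x$pool), x$max_features))
  cat(sprintf("  best AUC %.3f: %s\n", x$results$auc[1L],
              x$results$features[1L]))
  invisible(x)
}

#' Best classifier of a search
#'
#' @param task A `task_result`.
#' @return A list with the top-ranked combination's `features`, `auc`,
#'   `scores` (LOOCV probability vector), `labels` and its `coef_table`
#'   rows (odds ratios, Wald P-values).
#' @export
best_classifier <- function(task) {
  stopifnot(inherits(task, "task_result"))
  cid <- task$results$combo_id[1L]
  list(features = strsplit(task$results$features[1L], "+", fixed = TRUE)[[1]],
       auc = task$results$auc[1L],
       scores = stats::setNames(task$top_scores[, as.character(cid)],
                                rownames(task$top_scores)),
       labels = task$labels,
       coef_table = task$coef_table[task$coef_table$combo_id == cid, ,
                                    drop = FALSE])
}

#' Export search results to CSV
#'
#' One row per classifier with its AUC and flags; per-feature odds ratios
#' and P-values go to a companion `<path>_coefficients.csv`.
#'
#' @param task A `task_result`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_task_results <- function(task, path) {
  data.table::fwrite(task$results, path)
  coef_path <- sub("(\\.[^.]*)?$", "_coefficients\\1", path)
  data.table::fwrite(task$coef_table, coef_path)
  invisible(path)
}
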