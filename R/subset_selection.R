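# Label-blind feature subset selection: column-pivoted QR ordering with a
# condition-number cap on the standardized column prefix.

#' Standardize a feature matrix by its column means
#'
#' Default standardization divides each centred column by its own mean:
#' `x -> (x - mean) / mean`, making every feature dimensionless relative to
#' its cohort-average level. This mean-ratio scaling is undefined for
#' columns whose mean is (numerically) zero; such columns raise an error
#' naming the feature and pointing at the z-score option
#' (`method = "zscore"`, `(x - mean) / sd`).
#'
#' @param fm Numeric matrix (patients x features) with column names.
#' @param method `"mean_ratio"` (default) or `"zscore"`.
#' @return Matrix of the same shape with column means 0.
#' @export
#' @examples
#' standardize_features(cbind(a = c(2, 4, 6)))  # -0.5, 0, 0.5
standardize_features <- function(fm, method = c("mean_ratio", "zscore")) {
  method <- match.arg(method)
  x <- unclass(fm)
  stopifnot(is.matrix(x), is.numeric(x))
  mu <- colMeans(x)
  if (method == "mean_ratio") {
    scale_ref <- pmax(colMeans(abs(x)), .Machine$double.eps)
    zero <- abs(mu) < 1e-10 * scale_ref
    if (any(zero)) {
      stop("mean-ratio standardization undefined for zero-mean feature(s): ",
           paste(colnames(x)[zero], collapse = ", "),
           "; consider method = \"zscore\"", call. = FALSE)
    }
    out <- sweep(sweep(x, 2L, mu, "-"), 2L, mu, "/")
  } else {
    sd <- apply(x, 2L, stats::sd)
    if (any(sd == 0)) {
      stop("z-score standardization undefined for constant feature(s): ",
           paste(colnames(x)[sd == 0], collapse = ", "), call. = FALSE)
    }
    out <- sweep(sweep(x, 2L, mu, "-"), 2L, sd, "/")
  }
  attr(out, "standardization") <- method
  out
}

#' Column-pivoted QR ordering of a standardized feature matrix
#'
#' Runs Householder QR with greedy column pivoting (at each step the column
#' with the largest residual norm is chosen; LAPACK `dgeqp3`), so that the
#' magnitudes of the diagonal of R are non-increasing and the first k
#' pivoted columns form the greedily most linearly independent k-subset.
#' Outcome labels are, by construction, never an input: selection is
#' label-blind.
#'
#' @param x Standardized numeric matrix (see [standardize_features()]).
#' @return An object of class `subset_selection` with `pivot_order`
#'   (column indices), `feature_names` (pivoted order), `r_diag`
#'   (|diag(R)|, non-increasing) and `rank_deficient` (logical per pivot
#'   position, flagged where `r_diag` is at machine-precision zero relative
#'   to the leading element). Condition numbers and the chosen subset are
#'   filled in by [choose_subset()].
#' @export
pivoted_qr_order <- function(x) {
  stopifnot(is.matrix(x), is.numeric(x))
  if (nrow(x) < ncol(x)) {
    warning("fewer patients (", nrow(x), ") than features (", ncol(x),
            "); trailing pivots are necessarily rank-deficient",
            call. = FALSE)
  }
  qx <- qr(x, LAPACK = TRUE)
  m <- min(dim(x))
  r_diag <- abs(diag(qr.R(qx))[seq_len(m)])
  pivot <- qx$pivot
  structure(list(
    pivot_order = pivot,
    feature_names = colnames(x)[pivot] %||% as.character(pivot),
    r_diag = r_diag,
    rank_deficient = r_diag <= max(dim(x)) * .Machine$double.eps * r_diag[1L],
    prefix_cond = NULL, chosen_k = NULL, chosen_features = NULL,
    cond_cap = NULL, n_features = ncol(x)
  ), class = "subset_selection")
}

#' Choose the largest well-conditioned column prefix
#'
#' For each prefix length k of the pivoted column order, computes the
#' 2-norm condition number (ratio of extreme singular values) of the
#' corresponding standardized columns, then selects the largest k whose
#' condition number does not exceed `cond_cap` (scanning k from the full
#' width downward, since prefix condition numbers need not be monotone in
#' pathological cases). The default cap of 15 sits within the commonly
#' recommended 10-20 range for limiting multicollinearity in regression
#' design matrices.
#'
#' @param sel A `subset_selection` from [pivoted_qr_order()].
#' @param x The same standardized matrix the ordering was computed from.
#' @param cond_cap Maximum acceptable condition number (default 15).
#' @return `sel` with `prefix_cond`, `chosen_k`, `chosen_features` and
#'   `cond_cap` filled in.
#' @export
choose_subset <- function(sel, x, cond_cap = 15) {
  stopifnot(inherits(sel, "subset_selection"), is.matrix(x),
            ncol(x) == sel$n_features, cond_cap >= 1)
  m <- length(sel$r_diag)
  prefix_cond <- vapply(seq_len(m), function(k) {
    d <- svd(x[, sel$pivot_order[seq_len(k)], drop = FALSE],
             nu = 0, nv = 0)$d
    if (min(d) == 0) Inf else max(d) / min(d)
  }, numeric(1))
  chosen_k <- NA_integer_
  for (k in rev(seq_len(m))) {
    if (is.finite(prefix_cond[k]) && prefix_cond[k] <= cond_cap) {
      chosen_k <- k
      break
    }
  }
  if (is.na(chosen_k)) {
    warning("no column prefix satisfies the condition-number cap; ",
            "falling back to a single feature", call. = FALSE)
    chosen_k <- 1L
  }
  sel$prefix_cond <- prefix_cond
  sel$chosen_k <- chosen_k
  sel$chosen_features <- sel$feature_names[seq_len(chosen_k)]
  sel$cond_cap <- cond_cap
  sel
}

#' Label-blind subset selection for a feature matrix
#'
#' Convenience wrapper: standardizes the matrix, computes the pivoted-QR
#' column ordering and selects the largest prefix whose condition number
#' stays within the cap. Run once on all records possessing complete
#' features, irrespective of outcome availability, so both outcomes share
#' the same subsets.
#'
#' @param fm Numeric feature matrix (patients x features, named columns).
#' @param cond_cap Maximum acceptable condition number (default 15).
#' @param standardization Passed to [standardize_features()].
#' @return A completed `subset_selection` object.
#' @export
#' @examples
#' set.seed(1)
#' fm <- cbind(a = rnorm(30, 10), b = rnorm(30, 5), c = rnorm(30, 2))
#' select_feature_subset(fm)$chosen_features
select_feature_subset <- function(fm, cond_cap = 15,
                                  standardization = c("mean_ratio",
                                                      "zscore")) {
  x <- standardize_features(fm, method = standardization)
  sel <- pivoted_qr_order(x)
  choose_subset(sel, x, cond_cap = cond_cap)
}

#' @export
print.subset_selection <- function(x, ...) {
  cat(sprintf("<subset_selection> %d features", x$n_features))
  if (!is.null(x$chosen_k)) {
    cat(sprintf(", chose %d (condition number %.2f <= cap %g)",
                x$chosen_k, x$prefix_cond[x$chosen_k], x$cond_cap))
  }
  cat("\n")
  if (!is.null(x$chosen_features)) {
    cat("  ", paste(x$chosen_features, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Export a subset-selection report
#'
#' Writes the per-pivot diagnostics (pivot order, |diag(R)|, prefix
#' condition numbers) as CSV and, optionally, the chosen feature list as
#' plain text for downstream model search.
#'
#' @param sel A completed `subset_selection`.
#' @param path Output CSV path for the diagnostics table.
#' @param features_path Optional path for the chosen-feature list (one name
#'   per line).
#' @return Invisibly, the diagnostics data.frame.
#' @export
write_selection_report <- function(sel, path, features_path = NULL) {
  df <- data.frame(position = seq_along(sel$pivot_order),
                   pivot = sel$pivot_order,
                   feature = sel$feature_names,
                   r_diag = sel$r_diag[seq_along(sel$pivot_order)],
                   prefix_cond = sel$prefix_cond[seq_along(sel$pivot_order)],
                   chosen = seq_along(sel$pivot_order) <= sel$chosen_k)
  data.table::fwrite(df, path)
  if (!is.null(features_path)) {
    writeLines(sel$chosen_features, features_path)
  }
  invisible(df)
}
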