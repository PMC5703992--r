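# ROC/AUC evaluation: Mann-Whitney AUC, BCa bootstrap confidence intervals,
# DeLong paired AUC comparison and feature-inclusion-frequency summaries.

# Midrank AUC without validation; y_cases is a logical vector.
.auc_fast <- function(scores, y_cases) {
  n1 <- sum(y_cases)
  n0 <- length(scores) - n1
  r <- rank(scores)
  (sum(r[y_cases]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the ROC curve
#'
#' AUC of a score vector against binary labels, computed as the
#' Mann-Whitney statistic: the fraction of (case, control) pairs in which
#' the case outscores the control, ties counting one half. Equivalent to
#' the area under the ROC curve swept over all distinct score thresholds
#' (no binning).
#'
#' @param scores Numeric score vector (e.g. predicted outcome
#'   probabilities); any strictly monotone transform gives the same AUC.
#' @param labels Binary 0/1 vector; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' roc_auc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0))  # 1
roc_auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  if (length(unique(labels)) < 2L) {
    stop("AUC undefined: labels contain a single class", call. = FALSE)
  }
  .auc_fast(as.numeric(scores), labels == 1)
}

# BCa interval endpoints from a bootstrap distribution and the
# bias-correction / acceleration constants. Exposed internally so the
# degenerate case (z0 = 0, a = 0 => plain percentile interval) is directly
# checkable.
.bca_endpoints <- function(boot, z0, a, conf = 0.95) {
  alpha <- (1 - conf) / 2
  adj <- function(al) {
    zal <- stats::qnorm(al)
    stats::pnorm(z0 + (z0 + zal) / (1 - a * (z0 + zal)))
  }
  stats::quantile(boot, probs = c(adj(alpha), adj(1 - alpha)), names = FALSE,
                  type = 7)
}

#' BCa bootstrap confidence interval for an AUC
#'
#' Patient-level bootstrap of the (score, label) pairs with
#' bias-corrected and accelerated (BCa) endpoints: the bias correction z0
#' is estimated from the fraction of bootstrap AUCs below the point
#' estimate, and the acceleration a from the skewness of leave-one-out
#' jackknife AUCs. Bootstrap replicates that lose one class entirely are
#' redrawn (and counted). Deterministic given `seed`.
#'
#' @inheritParams roc_auc
#' @param n_boot Number of bootstrap replicates (default 1000; at least
#'   200).
#' @param seed Integer seed for the resampling; `NULL` uses the current RNG
#'   stream.
#' @param conf Confidence level (default 0.95).
#' @return Object of class `roc_ci`: list with `auc`, `ci_low`, `ci_high`,
#'   `n_boot`, `seed`, `conf`, `n_redrawn` (single-class replicates
#'   redrawn) and `degenerate` (`TRUE` if the interval fails to bracket
#'   the point estimate, which is logged rather than hidden).
#' @export
bca_ci <- function(scores, labels, n_boot = 1000, seed = NULL, conf = 0.95) {
  labels <- as.numeric(labels)
  scores <- as.numeric(scores)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)),
            n_boot >= 200)
  y_cases <- labels == 1
  if (sum(y_cases) < 2L || sum(!y_cases) < 2L) {
    stop("BCa interval requires at least 2 cases and 2 controls",
         call. = FALSE)
  }
  theta <- .auc_fast(scores, y_cases)
  n <- length(scores)

  run <- function() {
    boot <- numeric(n_boot)
    n_redrawn <- 0L
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        yb <- y_cases[idx]
        if (any(yb) && !all(yb)) break
        n_redrawn <- n_redrawn + 1L
      }
      boot[b] <- .auc_fast(scores[idx], yb)
    }
    list(boot = boot, n_redrawn = n_redrawn)
  }
  res <- if (is.null(seed)) run() else with_seed(seed, run())
  boot <- res$boot

  frac_below <- (sum(boot < theta) + 0.5 * sum(boot == theta)) / n_boot
  frac_below <- min(max(frac_below, 1 / (n_boot + 1)), n_boot / (n_boot + 1))
  z0 <- stats::qnorm(frac_below)
  jack <- vapply(seq_len(n), function(i) {
    .auc_fast(scores[-i], y_cases[-i])
  }, numeric(1))
  d <- mean(jack) - jack
  denom <- sum(d^2)^1.5
  a <- if (denom == 0) 0 else sum(d^3) / (6 * denom)

  ends <- .bca_endpoints(boot, z0, a, conf)
  degenerate <- !(ends[1] <= theta && theta <= ends[2])
  structure(list(auc = theta, ci_low = ends[1], ci_high = ends[2],
                 n_boot = n_boot, seed = seed, conf = conf,
                 n_redrawn = res$n_redrawn, degenerate = degenerate),
            class = "roc_ci")
}

#' @export
print.roc_ci <- function(x, ...) {
  cat(sprintf("AUC %.3f (%.0f%% BCa CI: %.3f-%.3f; %d bootstrap replicates)\n",
              x$auc, 100 * x$conf, x$ci_low, x$ci_high, x$n_boot))
  invisible(x)
}

# Placement values: for each case, the fraction of controls it beats
# (ties = 1/2), and symmetrically for controls.
.placements <- function(scores, y_cases) {
  sc <- scores[y_cases]
  sn <- scores[!y_cases]
  psi <- outer(sc, sn, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi))
}

#' DeLong test for two correlated AUCs
#'
#' Nonparametric comparison of the AUCs of two score vectors evaluated on
#' the same patients (paired design), using the DeLong structural
#' components: per-case and per-control placement values whose empirical
#' covariances give the variance of the AUC difference. Identical score
#' vectors (zero variance of the difference) return P = 1 and are flagged.
#'
#' @param scores_a,scores_b Score vectors for the two classifiers, same
#'   patients in the same order.
#' @param labels Binary 0/1 vector shared by both.
#' @return Object of class `delong_test`: `auc_a`, `auc_b`, `delta`,
#'   `var_delta`, `z`, `p_value` (two-sided normal), `degenerate`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  labels <- as.numeric(labels)
  stopifnot(length(scores_a) == length(labels),
            length(scores_b) == length(labels), all(labels %in% c(0, 1)))
  y_cases <- labels == 1
  n1 <- sum(y_cases)
  n0 <- sum(!y_cases)
  if (n1 < 2L || n0 < 2L) {
    stop("DeLong test requires at least 2 cases and 2 controls",
         call. = FALSE)
  }
  pa <- .placements(as.numeric(scores_a), y_cases)
  pb <- .placements(as.numeric(scores_b), y_cases)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_delta <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / n1 +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n0
  delta <- pa$auc - pb$auc
  degenerate <- var_delta <= 0
  if (degenerate) {
    z <- 0
    p <- 1
  } else {
    z <- delta / sqrt(var_delta)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(auc_a = pa$auc, auc_b = pb$auc, delta = delta,
                 var_delta = var_delta, z = z, p_value = p,
                 degenerate = degenerate),
            class = "delong_test")
}

#' @export
print.delong_test <- function(x, ...) {
  cat(sprintf("DeLong test: AUC %.3f vs %.3f (z = %.3f, P = %.4f)%s\n",
              x$auc_a, x$auc_b, x$z, x$p_value,
              if (x$degenerate) " [degenerate: identical scores]" else ""))
  invisible(x)
}

#' DeLong variance of a single AUC
#'
#' Placement-value variance estimate `var(V10)/n1 + var(V01)/n0` of one
#' AUC, the single-curve special case of the DeLong covariance structure.
#'
#' @inheritParams roc_auc
#' @return Variance estimate of the AUC.
#' @export
delong_auc_variance <- function(scores, labels) {
  labels <- as.numeric(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  y_cases <- labels == 1
  n1 <- sum(y_cases)
  n0 <- sum(!y_cases)
  if (n1 < 2L || n0 < 2L) {
    stop("variance estimate requires at least 2 cases and 2 controls",
         call. = FALSE)
  }
  p <- .placements(as.numeric(scores), y_cases)
  stats::var(p$v10) / n1 + stats::var(p$v01) / n0
}

#' Feature inclusion frequency among high-performing classifiers
#'
#' For each pool feature, counts the classifiers with AUC above
#' `auc_threshold` in which the feature appears with Wald P below
#' `p_threshold` (from the full-data multivariate fit), and splits those
#' inclusions by the direction of the feature's odds ratio. A feature
#' whose bar is "monotone" (all inclusions on one side of OR = 1) is
#' associated with risk in a single direction across all high performers.
#' Features never included at significance are listed with zero.
#'
#' @param task A `task_result` from [run_task()].
#' @param auc_threshold AUC cut-off defining high performers (default 0.7,
#'   the approximate ceiling of preoperative-score-based mortality
#'   prediction in this surgical setting).
#' @param p_threshold Wald significance level (default 0.05).
#' @return data.frame with one row per pool feature, sorted by
#'   `n_high_performers` descending: `feature`, `n_high_performers`,
#'   `frac_or_gt_1`, `frac_or_lt_1` (fractions sum to 1 where the count is
#'   positive; `NA` where it is zero).
#' @export
inclusion_frequency <- function(task, auc_threshold = 0.7,
                                p_threshold = 0.05) {
  stopifnot(inherits(task, "task_result"))
  high <- task$results$combo_id[task$results$auc > auc_threshold]
  if (!length(high)) {
    warning("no classifier exceeds AUC ", auc_threshold, call. = FALSE)
    return(data.frame(feature = character(), n_high_performers = integer(),
                      frac_or_gt_1 = numeric(), frac_or_lt_1 = numeric(),
                      stringsAsFactors = FALSE))
  }
  ct <- task$coef_table
  sig <- ct[ct$combo_id %in% high & ct$p_value < p_threshold, , drop = FALSE]
  rows <- lapply(task$pool, function(f) {
    sub <- sig[sig$feature == f, , drop = FALSE]
    n <- nrow(sub)
    data.frame(feature = f, n_high_performers = n,
               frac_or_gt_1 = if (n) mean(sub$odds_ratio > 1) else NA_real_,
               frac_or_lt_1 = if (n) mean(sub$odds_ratio < 1) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$n_high_performers, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pairwise DeLong comparison of the best classifiers across tasks
#'
#' Compares, pairwise, the best AUC achieved in each task on the same
#' patient cohort (within one outcome): all tasks must score the identical
#' patient set.
#'
#' @param scores_list Named list of per-patient score vectors (one per
#'   task), each named by patient id.
#' @param labels Binary 0/1 vector named by patient id.
#' @param sig_level Significance threshold for the `significant` flag
#'   (default 0.05).
#' @return data.frame with one row per task pair: `task_a`, `task_b`,
#'   `auc_a`, `auc_b`, `z`, `p_value`, `significant`.
#' @export
compare_tasks <- function(scores_list, labels, sig_level = 0.05) {
  stopifnot(is.list(scores_list), length(scores_list) >= 2,
            !is.null(names(scores_list)))
  ids <- names(labels)
  if (is.null(ids)) stop("labels must be named by patient id", call. = FALSE)
  for (nm in names(scores_list)) {
    s <- scores_list[[nm]]
    if (is.null(names(s)) || !setequal(names(s), ids)) {
      stop("task ", nm, " scores a different patient set than the labels",
           call. = FALSE)
    }
    scores_list[[nm]] <- s[ids]
  }
  pairs <- utils::combn(names(scores_list), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]
    b <- pairs[2, j]
    dt <- delong_test(scores_list[[a]], scores_list[[b]], labels)
    data.frame(task_a = a, task_b = b, auc_a = dt$auc_a, auc_b = dt$auc_b,
               z = dt$z, p_value = dt$p_value,
               significant = dt$p_value < sig_level,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
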