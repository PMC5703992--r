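# End-to-end orchestration: filters -> feature matrix -> label-blind subset
# selection -> exhaustive classifier search -> best-classifier inference.

.GROUP_SETS <- list(
  preop_only = "preoperative",
  intraop_only = c("hemodynamic", "nonhemodynamic"),
  combined = c("preoperative", "hemodynamic", "nonhemodynamic"),
  nonhemo_only = "nonhemodynamic"
)

#' Run one outcome-prediction task end to end
#'
#' Applies the record-inclusion filters, builds the feature matrix for the
#' requested feature group, performs label-blind subset selection on all
#' feature-complete records (irrespective of outcome availability, so both
#' outcomes share subsets), exhaustively searches all classifiers of up to
#' `max_features` selected features with leave-one-out cross-validation on
#' the outcome-labeled records, and computes a BCa bootstrap confidence
#' interval for the best classifier's AUC.
#'
#' @param records Named list of [patient_record()]s.
#' @param outcome `"mortality"` or `"arf"`.
#' @param feature_group One of `"combined"`, `"preop_only"`,
#'   `"intraop_only"`, `"nonhemo_only"`.
#' @param cond_cap Condition-number cap for subset selection (default 15).
#' @param max_features Maximum features per classifier (default 5).
#' @param top_n Classifiers whose score vectors are retained (default 100).
#' @param n_boot BCa bootstrap replicates (default 1000).
#' @param seed Seed for the bootstrap stream (default 1; child seeds are
#'   derived per outcome and feature group).
#' @param min_signal_minutes,max_gap_s Inclusion-filter settings.
#' @param signals Signals the cohort carries (default: all 16); synthetic
#'   cohorts may simulate fewer.
#' @inheritParams hd_signals
#' @return Object of class `hd_task_report`: the inclusion filter result,
#'   the `subset_selection`, the `task_result`, the best classifier and
#'   its `roc_ci`.
#' @export
analyze_cohort <- function(records, outcome,
                           feature_group = c("combined", "preop_only",
                                             "intraop_only", "nonhemo_only"),
                           cond_cap = 15, max_features = 5, top_n = 100,
                           n_boot = 1000, seed = 1,
                           min_signal_minutes = 180, max_gap_s = 60,
                           signals = NULL,
                           svi_direction = c("below", "above")) {
  feature_group <- match.arg(feature_group)
  outcome <- match.arg(outcome, .OUTCOMES)
  svi_direction <- match.arg(svi_direction)

  # Feature-completeness filter (label-blind): selection uses every record
  # possessing all features, with or without this outcome's label.
  complete <- apply_inclusion_filters(records, outcome = NULL,
                                      min_signal_minutes = min_signal_minutes,
                                      max_gap_s = max_gap_s,
                                      required_signals = signals)
  fm <- build_feature_matrix(complete$included,
                             groups = .GROUP_SETS[[feature_group]],
                             signals = signals, max_gap_s = max_gap_s,
                             svi_direction = svi_direction)
  sel <- select_feature_subset(fm, cond_cap = cond_cap)

  labeled <- Filter(function(r) !is.na(r$outcomes[[outcome]]),
                    complete$included)
  if (length(labeled) < 10L) {
    stop("fewer than 10 outcome-labeled records after filtering",
         call. = FALSE)
  }
  y <- vapply(labeled, function(r) r$outcomes[[outcome]], numeric(1))
  x <- unclass(fm)[names(labeled), , drop = FALSE]

  task <- run_task(x, y, pool = sel$chosen_features,
                   max_features = max_features, top_n = top_n)
  best <- best_classifier(task)
  ci <- bca_ci(best$scores, y, n_boot = n_boot,
               seed = derive_seed(seed, "bca", outcome, feature_group))

  structure(list(outcome = outcome, feature_group = feature_group,
                 n_complete = length(complete$included),
                 n_labeled = length(labeled),
                 n_cases = sum(y),
                 exclusions = complete$exclusions,
                 selection = sel, task = task, best = best, best_ci = ci,
                 seed = seed),
            class = "hd_task_report")
}

#' @export
print.hd_task_report <- function(x, ...) {
  cat(sprintf("<hd_task_report> outcome: %s, features: %s\n", x$outcome,
              x$feature_group))
  cat(sprintf("  %d labeled records (%d cases, %.1f%%); pool of %d ",
              x$n_labeled, x$n_cases, 100 * x$n_cases / x$n_labeled,
              length(x$selection$chosen_features)))
  cat(sprintf("selected features; %d classifiers searched\n",
              nrow(x$task$results)))
  cat(sprintf("  best AUC %.2f (95%% CI: %.2f-%.2f): %s\n", x$best$auc,
              x$best_ci$ci_low, x$best_ci$ci_high,
              paste(x$best$features, collapse = " + ")))
  ct <- x$best$coef_table
  for (i in seq_len(nrow(ct))) {
    cat(sprintf("    %-22s OR %.3f (%.3f-%.3f)  P = %.3f\n", ct$feature[i],
                ct$odds_ratio[i], ct$or_lower[i], ct$or_upper[i],
                ct$p_value[i]))
  }
  invisible(x)
}

#' Outcome prevalence as a printed percentage
#'
#' @param n_cases Number of outcome cases.
#' @param n_total Cohort size.
#' @param digits Decimal places (default 1).
#' @return Percentage, rounded.
#' @export
#' @examples
#' prevalence_pct(11, 62)  # 17.7
prevalence_pct <- function(n_cases, n_total, digits = 1) {
  stopifnot(n_total > 0, n_cases >= 0, n_cases <= n_total)
  round(100 * n_cases / n_total, digits)
}

#' Compare the best classifiers of several task reports
#'
#' Pairwise DeLong comparison of the best AUCs achieved by different
#' feature groups for the same outcome on the same labeled cohort.
#'
#' @param reports List of `hd_task_report`s sharing outcome and patients.
#' @param sig_level Significance threshold (default 0.05).
#' @return The pairwise comparison data.frame of [compare_tasks()].
#' @export
compare_task_reports <- function(reports, sig_level = 0.05) {
  stopifnot(length(reports) >= 2,
            all(vapply(reports, inherits, logical(1), "hd_task_report")))
  ocs <- unique(vapply(reports, `[[`, character(1), "outcome"))
  if (length(ocs) != 1L) {
    stop("reports mix outcomes: ", paste(ocs, collapse = ", "),
         call. = FALSE)
  }
  scores <- lapply(reports, function(r) r$best$scores)
  names(scores) <- vapply(reports, `[[`, character(1), "feature_group")
  labels <- reports[[1L]]$best$labels
  compare_tasks(scores, labels, sig_level = sig_level)
}
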