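# Per-signal waveform features: median, MAD, threshold-exposure area.

#' Median of a waveform signal
#'
#' Sample median of the recorded values (mean of the central pair for even
#' counts), capturing the central tendency of the signal over the surgery.
#'
#' @param signal A [waveform_signal()].
#' @return Median in signal units.
#' @export
extract_median <- function(signal) {
  stopifnot(inherits(signal, "waveform_signal"))
  if (!length(signal$values)) {
    stop("cannot take the median of an empty series (", signal$signal_id,
         ")", call. = FALSE)
  }
  stats::median(signal$values)
}

#' Median absolute deviation of a waveform signal
#'
#' `median(|x - median(x)|)`, the robust variability feature for
#' continuously recorded signals. Reported raw, without the 1.4826
#' normal-consistency factor. Defined only for continuous signals;
#' intermittently computed indices contribute a median only.
#'
#' @param signal A continuous [waveform_signal()].
#' @return MAD in signal units.
#' @export
extract_mad <- function(signal) {
  stopifnot(inherits(signal, "waveform_signal"))
  if (signal$kind != "continuous") {
    stop("MAD is not defined for intermittent signal ", signal$signal_id,
         call. = FALSE)
  }
  if (!length(signal$values)) {
    stop("cannot take the MAD of an empty series (", signal$signal_id, ")",
         call. = FALSE)
  }
  stats::mad(signal$values, constant = 1)
}

#' Covered recording time of a signal
#'
#' Sum of inter-sample intervals with each interval capped at `max_gap_s`,
#' in minutes. Long dropouts therefore contribute at most one capped
#' interval rather than their full span, consistent with the exposure-area
#' integration rule.
#'
#' @param signal A [waveform_signal()].
#' @param max_gap_s Gap cap in seconds (default 60).
#' @return Covered minutes (0 for series with fewer than two samples).
#' @export
signal_coverage_minutes <- function(signal, max_gap_s = 60) {
  stopifnot(inherits(signal, "waveform_signal"))
  if (length(signal$times) < 2L) return(0)
  sum(pmin(diff(signal$times), max_gap_s)) / 60
}

#' Time-integrated threshold-exposure area
#'
#' Integrates the excursion of a continuous signal beyond its "normal"
#' threshold on the harmful side, yielding a measure of the patient's total
#' exposure to the putatively dangerous condition in signal-unit times
#' minutes (e.g. mmHg·min of CVP above 5 mmHg).
#'
#' Each sample is held as a rectangle until the next sample, with the
#' holding interval capped at `max_gap_s` so recording dropouts do not
#' accumulate area; the final sample is held for the series' median
#' inter-sample interval (also capped). A constant series at level `c`
#' therefore yields exactly `|c - threshold| * covered-minutes` on the
#' harmful side and 0 on the safe side. A trapezoidal rule is available as
#' an option.
#'
#' @param signal A continuous [waveform_signal()] with at least 2 samples.
#' @param spec Threshold specification: list with `threshold` and
#'   `direction` (`"above"`/`"below"` = the harmful side). Defaults to the
#'   registry entry for the signal ([threshold_spec()]).
#' @param max_gap_s Gap cap in seconds (default 60).
#' @param rule `"rectangle"` (default; monitors emit step-held values) or
#'   `"trapezoid"`.
#' @return Non-negative exposure area in signal-unit·minutes.
#' @export
#' @examples
#' w <- waveform_signal("CVP", times = seq(0, 590, by = 10),
#'                      values = rep(8, 60))
#' extract_exposure_area(w)  # (8 - 5) mmHg * 10 min = 30 mmHg.min
extract_exposure_area <- function(signal, spec = NULL, max_gap_s = 60,
                                  rule = c("rectangle", "trapezoid")) {
  stopifnot(inherits(signal, "waveform_signal"))
  rule <- match.arg(rule)
  if (signal$kind != "continuous") {
    stop("exposure area is not defined for intermittent signal ",
         signal$signal_id, call. = FALSE)
  }
  if (length(signal$values) < 2L) {
    stop("exposure area requires at least 2 samples (", signal$signal_id,
         ")", call. = FALSE)
  }
  if (is.null(spec)) spec <- threshold_spec(signal$signal_id)
  s <- if (spec$direction == "above") 1 else -1
  exc <- pmax(0, s * (signal$values - spec$threshold))

  gaps <- diff(signal$times)
  if (all(gaps > max_gap_s)) {
    warning("all inter-sample intervals of ", signal$signal_id,
            " exceed the gap cap; area computed from capped intervals only",
            call. = FALSE)
  }
  tail_dt <- min(stats::median(gaps), max_gap_s)
  dt_min <- c(pmin(gaps, max_gap_s), tail_dt) / 60
  if (rule == "rectangle") {
    sum(exc * dt_min)
  } else {
    n <- length(exc)
    mid <- (exc[-n] + exc[-1L]) / 2
    sum(mid * dt_min[-n]) + exc[n] * dt_min[n]
  }
}

#' Normalize raw volumes to body mass
#'
#' Helper for cohort tables recording raw administered volumes in mL: the
#' analysis expects blood-product volumes already normalized to mL/kg.
#'
#' @param volume_ml Raw volume(s) in mL.
#' @param weight_kg Patient weight in kg.
#' @return Volume(s) in mL/kg.
#' @export
volume_per_kg <- function(volume_ml, weight_kg) {
  stopifnot(weight_kg > 0)
  volume_ml / weight_kg
}

#' Build the patients-by-features analysis matrix
#'
#' Assembles the feature matrix over included records for the requested
#' feature groups, in the canonical column order of
#' [hd_feature_registry()]: preoperative features as recorded, hemodynamic
#' features computed from the waveforms (median for every signal, MAD and
#' threshold-exposure area for continuous signals), and the non-hemodynamic
#' intraoperative features. All three groups together give the full
#' 56-column matrix. Records must have passed [apply_inclusion_filters()];
#' a missing value for any requested feature is an error, never silently
#' dropped or imputed.
#'
#' @param records List of included [patient_record()] objects.
#' @param groups Feature groups to include.
#' @param signals Signals contributing hemodynamic features (default: all
#'   16).
#' @param max_gap_s Gap cap in seconds passed to the area/coverage rules.
#' @inheritParams hd_signals
#' @return A numeric matrix (patients x features) of class
#'   `feature_matrix`; rownames are patient ids, and attribute
#'   `group_tags` gives each column's feature group.
#' @export
build_feature_matrix <- function(records,
                                 groups = c("preoperative", "hemodynamic",
                                            "nonhemodynamic"),
                                 signals = NULL, max_gap_s = 60,
                                 svi_direction = c("below", "above")) {
  records <- .as_record_list(records)
  groups <- match.arg(groups, several.ok = TRUE)
  svi_direction <- match.arg(svi_direction)
  reg <- hd_feature_registry(groups = groups, signals = signals,
                             svi_direction = svi_direction)
  sig_reg <- hd_signals(svi_direction = svi_direction)

  one_record <- function(r) {
    vapply(seq_len(nrow(reg)), function(j) {
      grp <- reg$group[j]
      if (grp == "preoperative") {
        v <- r$preop[[reg$name[j]]]
        if (is.na(v)) stop("record ", r$patient_id,
                           " is missing preoperative feature ", reg$name[j],
                           "; apply inclusion filters first", call. = FALSE)
        return(v)
      }
      if (grp == "nonhemodynamic") {
        v <- r$nonhemo[[reg$name[j]]]
        if (is.na(v)) stop("record ", r$patient_id,
                           " is missing feature ", reg$name[j],
                           "; apply inclusion filters first", call. = FALSE)
        return(v)
      }
      sid <- reg$signal[j]
      w <- r$waveforms[[sid]]
      if (is.null(w)) stop("record ", r$patient_id, " is missing signal ",
                           sid, "; apply inclusion filters first",
                           call. = FALSE)
      switch(reg$stat[j],
             median = extract_median(w),
             mad = extract_mad(w),
             area = {
               row <- sig_reg[sig_reg$signal_id == sid, ]
               extract_exposure_area(
                 w, spec = list(threshold = row$threshold,
                                direction = row$direction),
                 max_gap_s = max_gap_s)
             })
    }, numeric(1))
  }

  m <- t(vapply(records, one_record, numeric(nrow(reg))))
  dimnames(m) <- list(unname(vapply(records, `[[`, character(1),
                                    "patient_id")),
                      reg$name)
  structure(m, group_tags = stats::setNames(reg$group, reg$name),
            class = c("feature_matrix", "matrix", "array"))
}

#' Export a feature matrix to CSV
#'
#' @param fm A `feature_matrix`.
#' @param path Output CSV path; patient ids go in a leading `patient_id`
#'   column.
#' @return Invisibly, `path`.
#' @export
write_feature_matrix <- function(fm, path) {
  df <- data.frame(patient_id = rownames(fm), fm, check.names = FALSE,
                   row.names = NULL)
  data.table::fwrite(df, path)
  invisible(path)
}

#' @export
print.feature_matrix <- function(x, ...) {
  tags <- attr(x, "group_tags")
  cat(sprintf("<feature_matrix> %d patients x %d features (%s)\n",
              nrow(x), ncol(x),
              paste(sprintf("%s: %d", names(table(tags)), table(tags)),
                    collapse = ", ")))
  invisible(x)
}
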