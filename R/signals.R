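# Registry of the intraoperative hemodynamic signals handled by the pipeline.
# Continuous signals carry a "normal" threshold and the harmful side of it;
# intermittently computed indices contribute a median only.
.SIGNALS <- data.frame(
  signal_id = c("SBP", "CVP", "HR", "SpO2", "dPmx", "PCCI", "PPV", "SVI",
                "SVRI", "SVV",
                "CFI", "ELWI", "GEDI", "GEF", "ITBI", "PVPI"),
  unit = c("mmHg", "mmHg", "bpm", "%", "mmHg/s", "L/min/m2", "%", "mL/m2",
           "dyn.s.cm-5.m2", "%",
           "1/min", "mL/kg", "mL/m2", "%", "mL/min/m2", "index"),
  kind = c(rep("continuous", 10), rep("intermittent", 6)),
  threshold = c(100, 5, 100, 90, 642, 3, 10, 40, 1700, 10, rep(NA_real_, 6)),
  direction = c("below", "above", "above", "below", "below", "below", "above",
                "below", "below", "above", rep(NA_character_, 6)),
  stringsAsFactors = FALSE
)

#' Hemodynamic signal registry
#'
#' Returns the table of supported intraoperative hemodynamic signals: units,
#' whether the monitor reports them continuously or intermittently, and for
#' continuous signals the "normal" threshold together with the harmful side
#' of it (the side whose excursions are integrated into the exposure-area
#' feature). Thresholds follow the bedside monitors' nominal normal ranges:
#' SBP below 100 mmHg, CVP above 5 mmHg, HR above 100 bpm, SpO2 below 90%,
#' dPmx below 642 mmHg/s, PCCI below 3 L/min/m2, PPV above 10%, SVI below
#' 40 mL/m2 (configurable, see `svi_direction`), SVRI below 1700
#' dyn.s.cm-5.m2 and SVV above 10%.
#'
#' @param svi_direction Harmful side for the stroke volume index exposure
#'   area, `"below"` (default: exposure to reduced stroke volume) or
#'   `"above"`.
#' @return A data.frame with columns `signal_id`, `unit`, `kind`,
#'   `threshold`, `direction`.
#' @export
#' @examples
#' hd_signals()
hd_signals <- function(svi_direction = c("below", "above")) {
  svi_direction <- match.arg(svi_direction)
  out <- .SIGNALS
  out$direction[out$signal_id == "SVI"] <- svi_direction
  out
}

#' Threshold specification for a continuous signal
#'
#' @param signal_id One of the continuous signal identifiers in
#'   [hd_signals()].
#' @inheritParams hd_signals
#' @return A list with elements `threshold` (signal units) and `direction`
#'   (`"above"` or `"below"`, the harmful side).
#' @export
threshold_spec <- function(signal_id, svi_direction = c("below", "above")) {
  reg <- hd_signals(svi_direction = match.arg(svi_direction))
  row <- reg[reg$signal_id == signal_id, , drop = FALSE]
  if (nrow(row) != 1L) {
    stop("unknown signal: ", signal_id, call. = FALSE)
  }
  if (row$kind != "continuous") {
    stop("signal ", signal_id,
         " is intermittent and has no threshold specification", call. = FALSE)
  }
  list(threshold = row$threshold, direction = row$direction)
}

#' Construct a waveform signal
#'
#' One patient's time-stamped series for a single hemodynamic variable.
#' Times are seconds from surgery start and must be strictly increasing;
#' values must be finite.
#'
#' @param signal_id Signal identifier; must appear in [hd_signals()].
#' @param times Numeric vector of sample times, seconds from surgery start.
#' @param values Numeric vector of sampled values, same length as `times`.
#' @return An object of class `waveform_signal`: a list with `signal_id`,
#'   `times`, `values` and `kind`.
#' @export
#' @examples
#' w <- waveform_signal("CVP", times = c(0, 10, 20), values = c(6, 7, 8))
#' w$kind
waveform_signal <- function(signal_id, times, values) {
  row <- .SIGNALS[.SIGNALS$signal_id == signal_id, , drop = FALSE]
  if (nrow(row) != 1L) stop("unknown signal: ", signal_id, call. = FALSE)
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values)) {
    stop("times and values must have equal length", call. = FALSE)
  }
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("timestamps for signal ", signal_id,
         " are not strictly increasing", call. = FALSE)
  }
  if (length(values) && any(!is.finite(values))) {
    stop("non-finite values in signal ", signal_id, call. = FALSE)
  }
  structure(list(signal_id = signal_id, times = times, values = values,
                 kind = row$kind),
            class = "waveform_signal")
}

#' @export
print.waveform_signal <- function(x, ...) {
  cat(sprintf("<waveform_signal> %s (%s), %d samples, %.1f min span\n",
              x$signal_id, x$kind, length(x$times),
              if (length(x$times) > 1) diff(range(x$times)) / 60 else 0))
  invisible(x)
}

# Field groupings of the cohort table -----------------------------------------

.PREOP_FEATURES <- c("age", "marginal_donor", "inr", "direct_bilirubin",
                     "total_bilirubin", "albumin", "creatinine", "meld",
                     "piggyback", "male", "diabetes", "hypertension",
                     "smoking", "asa_class", "bmi")
.PREOP_BINARY <- c("marginal_donor", "piggyback", "male", "diabetes",
                   "hypertension", "smoking")
.NONHEMO_FEATURES <- c("vol_whole_blood", "vol_ffp", "vol_platelets",
                       "vol_rbc_auto", "surgery_duration_min")
.VOLUME_FEATURES <- .NONHEMO_FEATURES[1:4]
.OUTCOMES <- c("mortality", "arf")

#' Construct a patient record
#'
#' Bundles one patient's preoperative features, non-hemodynamic
#' intraoperative features (blood-product volumes in mL/kg and surgery
#' duration in minutes), outcome labels and hemodynamic waveforms. Missing
#' values are represented as `NA` and are never imputed; record-level
#' completeness is enforced later by [apply_inclusion_filters()].
#'
#' @param patient_id Opaque patient identifier (character scalar).
#' @param preop Named numeric vector; any subset of the 15 preoperative
#'   features (`age`, `marginal_donor`, `inr`, `direct_bilirubin`,
#'   `total_bilirubin`, `albumin`, `creatinine`, `meld`, `piggyback`,
#'   `male`, `diabetes`, `hypertension`, `smoking`, `asa_class`, `bmi`).
#'   Binary comorbidities are coded 0/1; ASA class is an integer 1-4.
#' @param nonhemo Named numeric vector; `vol_whole_blood`, `vol_ffp`,
#'   `vol_platelets`, `vol_rbc_auto` (mL/kg, non-negative) and
#'   `surgery_duration_min` (> 0).
#' @param outcomes Named numeric vector over `mortality` and `arf`, each
#'   0, 1 or `NA`.
#' @param waveforms Named list of [waveform_signal()] objects, names equal
#'   to their `signal_id`.
#' @return An object of class `patient_record`.
#' @export
patient_record <- function(patient_id, preop = numeric(), nonhemo = numeric(),
                           outcomes = numeric(), waveforms = list()) {
  patient_id <- as.character(patient_id)
  preop <- .complete_named(preop, .PREOP_FEATURES, "preop")
  nonhemo <- .complete_named(nonhemo, .NONHEMO_FEATURES, "nonhemo")
  outcomes <- .complete_named(outcomes, .OUTCOMES, "outcomes")
  for (f in .PREOP_BINARY) {
    if (!is.na(preop[[f]]) && !preop[[f]] %in% c(0, 1)) {
      stop("binary preoperative field ", f, " must be 0 or 1 (patient ",
           patient_id, ")", call. = FALSE)
    }
  }
  for (f in .OUTCOMES) {
    if (!is.na(outcomes[[f]]) && !outcomes[[f]] %in% c(0, 1)) {
      stop("outcome ", f, " must be 0, 1 or NA (patient ", patient_id, ")",
           call. = FALSE)
    }
  }
  vols <- nonhemo[.VOLUME_FEATURES]
  if (any(!is.na(vols) & vols < 0)) {
    stop("blood-product volumes must be non-negative (patient ", patient_id,
         ")", call. = FALSE)
  }
  dur <- nonhemo[["surgery_duration_min"]]
  if (!is.na(dur) && dur <= 0) {
    stop("surgery duration must be positive (patient ", patient_id, ")",
         call. = FALSE)
  }
  if (length(waveforms)) {
    ok <- vapply(waveforms, inherits, logical(1), "waveform_signal")
    if (!all(ok)) stop("waveforms must be waveform_signal objects",
                       call. = FALSE)
    names(waveforms) <- vapply(waveforms, `[[`, character(1), "signal_id")
  }
  structure(list(patient_id = patient_id, preop = preop, nonhemo = nonhemo,
                 outcomes = outcomes, waveforms = waveforms),
            class = "patient_record")
}

# Fill a named vector out to the full field list, NA where absent.
.complete_named <- function(x, fields, what) {
  out <- stats::setNames(rep(NA_real_, length(fields)), fields)
  if (length(x)) {
    if (is.null(names(x)) || any(!nzchar(names(x)))) {
      stop(what, " values must be named", call. = FALSE)
    }
    unknown <- setdiff(names(x), fields)
    if (length(unknown)) {
      stop("unknown ", what, " field(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    out[names(x)] <- as.numeric(x)
  }
  out
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf("<patient_record> %s: %d/%d preop, %d/%d nonhemo, %d waveforms\n",
              x$patient_id, sum(!is.na(x$preop)), length(x$preop),
              sum(!is.na(x$nonhemo)), length(x$nonhemo), length(x$waveforms)))
  invisible(x)
}

#' Feature registry
#'
#' Enumerates, in the package's canonical column order, the features making
#' up the analysis feature matrix: 15 preoperative features, 36 hemodynamic
#' features (a median for all 16 signals plus MAD and threshold-exposure
#' area for the 10 continuous signals) and 5 non-hemodynamic intraoperative
#' features (four blood-product volumes and the surgery duration) -- 56 in
#' total.
#'
#' @param groups Feature groups to include, subset of `"preoperative"`,
#'   `"hemodynamic"`, `"nonhemodynamic"`.
#' @param signals Signals contributing hemodynamic features (default all 16
#'   registry signals); used by the synthetic-data tools when only a subset
#'   of channels is simulated.
#' @inheritParams hd_signals
#' @return A data.frame with columns `name` (machine name, e.g.
#'   `area_cvp_gt_5`), `group`, `signal` (`NA` for non-waveform features)
#'   and `stat` (`median`, `mad`, `area` or `NA`).
#' @export
#' @examples
#' nrow(hd_feature_registry())  # 56
hd_feature_registry <- function(groups = c("preoperative", "hemodynamic",
                                           "nonhemodynamic"),
                                signals = NULL,
                                svi_direction = c("below", "above")) {
  groups <- match.arg(groups, several.ok = TRUE)
  svi_direction <- match.arg(svi_direction)
  reg <- hd_signals(svi_direction = svi_direction)
  if (!is.null(signals)) {
    unknown <- setdiff(signals, reg$signal_id)
    if (length(unknown)) {
      stop("unknown signal(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    reg <- reg[reg$signal_id %in% signals, , drop = FALSE]
  }
  rows <- list()
  if ("preoperative" %in% groups) {
    rows[[length(rows) + 1L]] <- data.frame(
      name = .PREOP_FEATURES, group = "preoperative", signal = NA_character_,
      stat = NA_character_, stringsAsFactors = FALSE)
  }
  if ("hemodynamic" %in% groups && nrow(reg)) {
    for (i in seq_len(nrow(reg))) {
      sid <- reg$signal_id[i]
      lo <- tolower(sid)
      rows[[length(rows) + 1L]] <- data.frame(
        name = paste0("med_", lo), group = "hemodynamic", signal = sid,
        stat = "median", stringsAsFactors = FALSE)
      if (reg$kind[i] == "continuous") {
        cmp <- if (reg$direction[i] == "above") "gt" else "lt"
        area_name <- paste0("area_", lo, "_", cmp, "_",
                            format(reg$threshold[i], trim = TRUE))
        rows[[length(rows) + 1L]] <- data.frame(
          name = paste0("mad_", lo), group = "hemodynamic", signal = sid,
          stat = "mad", stringsAsFactors = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          name = area_name, group = "hemodynamic", signal = sid,
          stat = "area", stringsAsFactors = FALSE)
      }
    }
  }
  if ("nonhemodynamic" %in% groups) {
    rows[[length(rows) + 1L]] <- data.frame(
      name = .NONHEMO_FEATURES, group = "nonhemodynamic",
      signal = NA_character_, stat = NA_character_, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
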