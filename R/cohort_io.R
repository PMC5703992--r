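# Cohort and waveform file I/O plus record-level inclusion filtering.
#
# Column contracts:
#   cohort CSV    : patient_id, 15 preoperative columns, 5 non-hemodynamic
#                   columns, mortality, arf; one row per patient; missing
#                   value = empty cell.
#   waveform CSV  : patient_id, signal, time_s, value; long format, rows of
#                   one (patient, signal) series in time order.

.COHORT_COLUMNS <- function() {
  c("patient_id", .PREOP_FEATURES, .NONHEMO_FEATURES, .OUTCOMES)
}

#' Write a cohort to delimited text files
#'
#' Serializes patient records to the two-file contract read by
#' [load_cohort()]: a per-patient cohort table (missing values as empty
#' cells) and a long-format waveform table with one row per sample.
#'
#' @param records List of [patient_record()] objects.
#' @param cohort_path Path for the cohort CSV.
#' @param waveform_path Path for the long-format waveform CSV.
#' @return Invisibly, a list with the two paths.
#' @export
write_cohort <- function(records, cohort_path, waveform_path) {
  records <- .as_record_list(records)
  cohort <- data.table::rbindlist(lapply(records, function(r) {
    vals <- c(r$preop, r$nonhemo, r$outcomes)
    as.list(c(patient_id = r$patient_id,
              stats::setNames(fmt_num(vals), names(vals))))
  }))
  data.table::setcolorder(cohort, .COHORT_COLUMNS())
  data.table::fwrite(cohort, cohort_path, na = "", quote = FALSE)

  wf <- data.table::rbindlist(lapply(records, function(r) {
    if (!length(r$waveforms)) return(NULL)
    data.table::rbindlist(lapply(r$waveforms, function(w) {
      data.table::data.table(patient_id = r$patient_id,
                             signal = w$signal_id,
                             time_s = fmt_num(w$times),
                             value = fmt_num(w$values))
    }))
  }))
  if (!nrow(wf)) {
    wf <- data.table::data.table(patient_id = character(),
                                 signal = character(),
                                 time_s = character(), value = character())
  }
  data.table::fwrite(wf, waveform_path, quote = FALSE)
  invisible(list(cohort = cohort_path, waveforms = waveform_path))
}

#' Load a cohort from delimited text files
#'
#' Reads the cohort table and long-format waveform table written by
#' [write_cohort()] (or exported by any system honouring the same column
#' contract) into a list of [patient_record()] objects. Missing cohort
#' cells become `NA` and are never imputed. Unknown signal names, unknown
#' columns, non-numeric cells, duplicated timestamps and non-monotone
#' timestamps are rejected with errors naming the offending line, patient
#' or signal.
#'
#' @param cohort_path Path to the cohort CSV.
#' @param waveform_path Path to the waveform CSV, or `NULL` to load a
#'   cohort without waveforms.
#' @return Named list of `patient_record` objects, one per `patient_id`, in
#'   cohort-file order.
#' @export
load_cohort <- function(cohort_path, waveform_path = NULL) {
  if (!file.exists(cohort_path)) {
    stop("cohort file not found: ", cohort_path, call. = FALSE)
  }
  cohort <- utils::read.csv(cohort_path, colClasses = "character",
                            check.names = FALSE)
  expected <- .COHORT_COLUMNS()
  missing_cols <- setdiff(expected, names(cohort))
  if (length(missing_cols)) {
    stop("cohort file missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  unknown_cols <- setdiff(names(cohort), expected)
  if (length(unknown_cols)) {
    stop("cohort file has unknown column(s): ",
         paste(unknown_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(cohort$patient_id)) {
    stop("duplicate patient_id in cohort file: ",
         cohort$patient_id[duplicated(cohort$patient_id)][1L], call. = FALSE)
  }
  num <- lapply(setdiff(expected, "patient_id"), function(col) {
    raw <- cohort[[col]]
    x <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(x) & nzchar(trimws(raw)))
    if (length(bad)) {
      stop(sprintf("cohort file line %d: cannot parse %s value '%s'",
                   bad[1L] + 1L, col, raw[bad[1L]]), call. = FALSE)
    }
    x
  })
  names(num) <- setdiff(expected, "patient_id")

  wf_by_patient <- list()
  if (!is.null(waveform_path)) {
    if (!file.exists(waveform_path)) {
      stop("waveform file not found: ", waveform_path, call. = FALSE)
    }
    wf <- data.table::fread(waveform_path,
                            colClasses = list(character = c("patient_id",
                                                            "signal")))
    need <- c("patient_id", "signal", "time_s", "value")
    if (!identical(sort(names(wf)), sort(need))) {
      stop("waveform file must have columns patient_id, signal, time_s, value",
           call. = FALSE)
    }
    unknown_sig <- setdiff(unique(wf$signal), .SIGNALS$signal_id)
    if (length(unknown_sig)) {
      stop("unknown signal name(s) in waveform file: ",
           paste(unknown_sig, collapse = ", "), call. = FALSE)
    }
    unknown_pat <- setdiff(unique(wf$patient_id), cohort$patient_id)
    if (length(unknown_pat)) {
      stop("waveform file references patient(s) absent from cohort: ",
           paste(unknown_pat, collapse = ", "), call. = FALSE)
    }
    bad_num <- which(!is.finite(wf$time_s) | !is.finite(wf$value))
    if (length(bad_num)) {
      stop(sprintf("waveform file line %d: non-numeric time or value",
                   bad_num[1L] + 1L), call. = FALSE)
    }
    for (pid in unique(wf$patient_id)) {
      sub <- wf[wf$patient_id == pid, ]
      sigs <- list()
      for (sid in unique(sub$signal)) {
        ss <- sub[sub$signal == sid, ]
        d <- diff(ss$time_s)
        if (any(d == 0)) {
          stop(sprintf("duplicate timestamp for patient %s, signal %s",
                       pid, sid), call. = FALSE)
        }
        if (any(d < 0)) {
          stop(sprintf(
            "timestamps not strictly increasing for patient %s, signal %s",
            pid, sid), call. = FALSE)
        }
        sigs[[sid]] <- waveform_signal(sid, ss$time_s, ss$value)
      }
      wf_by_patient[[pid]] <- sigs
    }
  }

  records <- lapply(seq_len(nrow(cohort)), function(i) {
    pid <- cohort$patient_id[i]
    grab <- function(fields) {
      stats::setNames(vapply(fields, function(f) num[[f]][i], numeric(1)),
                      fields)
    }
    patient_record(
      patient_id = pid,
      preop = grab(.PREOP_FEATURES),
      nonhemo = grab(.NONHEMO_FEATURES),
      outcomes = grab(.OUTCOMES),
      waveforms = wf_by_patient[[pid]] %||% list()
    )
  })
  names(records) <- cohort$patient_id
  records
}

#' Apply record-level inclusion filters
#'
#' A record is retained only if it could contribute all 56 analysis
#' features and (when `outcome` is given) carries the requested outcome
#' label: all 15 preoperative features present, all four blood-product
#' volumes and the surgery duration present, every required continuous
#' signal covering at least `min_signal_minutes` of data, every required
#' intermittent signal having at least one sample. Coverage is the sum of
#' inter-sample intervals with each interval capped at `max_gap_s`
#' (consistent with the exposure-area integration rule), so long dropouts
#' do not count as covered time. Each excluded record is logged with its
#' first failing reason.
#'
#' @param records List of [patient_record()] objects.
#' @param outcome `"mortality"`, `"arf"`, or `NULL` to filter on feature
#'   completeness only (as used for label-blind subset selection).
#' @param min_signal_minutes Minimum covered minutes per continuous signal
#'   (default 180).
#' @param max_gap_s Gap cap in seconds for the coverage computation
#'   (default 60).
#' @param required_signals Signals every record must carry; defaults to all
#'   16 registry signals.
#' @return A list with `included` (named list of records), `exclusions`
#'   (data.frame `patient_id`, `reason`) and the filter settings.
#' @export
apply_inclusion_filters <- function(records, outcome = NULL,
                                    min_signal_minutes = 180,
                                    max_gap_s = 60,
                                    required_signals = NULL) {
  records <- .as_record_list(records)
  if (!is.null(outcome)) {
    outcome <- match.arg(outcome, .OUTCOMES)
  }
  reg <- hd_signals()
  if (is.null(required_signals)) required_signals <- reg$signal_id
  reg <- reg[reg$signal_id %in% required_signals, , drop = FALSE]

  reason_for <- function(r) {
    miss_pre <- .PREOP_FEATURES[is.na(r$preop)]
    if (length(miss_pre)) {
      return(paste0("missing preoperative feature: ", miss_pre[1L]))
    }
    miss_vol <- .VOLUME_FEATURES[is.na(r$nonhemo[.VOLUME_FEATURES])]
    if (length(miss_vol)) {
      return(paste0("missing blood product volume: ", miss_vol[1L]))
    }
    if (is.na(r$nonhemo[["surgery_duration_min"]])) {
      return("missing surgery duration")
    }
    for (i in seq_len(nrow(reg))) {
      sid <- reg$signal_id[i]
      w <- r$waveforms[[sid]]
      if (is.null(w) || length(w$times) == 0L) {
        return(paste0("missing signal: ", sid))
      }
      if (reg$kind[i] == "continuous") {
        cov <- signal_coverage_minutes(w, max_gap_s = max_gap_s)
        if (cov < min_signal_minutes) {
          return(sprintf("signal %s < %g min", sid, min_signal_minutes))
        }
      }
    }
    if (!is.null(outcome) && is.na(r$outcomes[[outcome]])) {
      return(paste0("missing outcome: ", outcome))
    }
    NA_character_
  }

  reasons <- vapply(records, reason_for, character(1))
  keep <- is.na(reasons)
  included <- records[keep]
  exclusions <- data.frame(
    patient_id = vapply(records[!keep], `[[`, character(1), "patient_id"),
    reason = reasons[!keep],
    stringsAsFactors = FALSE, row.names = NULL)
  if (!length(included)) {
    stop("no records pass the inclusion filters; check filter settings ",
         "and data completeness", call. = FALSE)
  }
  list(included = included, exclusions = exclusions, outcome = outcome,
       min_signal_minutes = min_signal_minutes, max_gap_s = max_gap_s)
}

#' Write an exclusion log
#'
#' @param filtered Result of [apply_inclusion_filters()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_exclusion_log <- function(filtered, path) {
  data.table::fwrite(filtered$exclusions, path)
  invisible(path)
}

.as_record_list <- function(records) {
  if (inherits(records, "patient_record")) records <- list(records)
  if (!is.list(records) ||
      !all(vapply(records, inherits, logical(1), "patient_record"))) {
    stop("records must be a list of patient_record objects", call. = FALSE)
  }
  names(records) <- vapply(records, `[[`, character(1), "patient_id")
  records
}
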