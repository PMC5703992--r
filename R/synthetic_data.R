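# Synthetic cohort generator: autocorrelated multichannel intraoperative
# waveforms, correlated preoperative laboratory values, blood-product
# volumes, and binary outcomes from a logistic link with known
# coefficients. Parameter defaults are chosen for statistical realism and
# test utility (plausible baseline levels, sustained threshold crossings,
# realistic multicollinearity), not for clinical fidelity.

# Per-signal simulation defaults: population baseline mean and SD (between
# patients), marginal SD of the within-surgery AR(1) fluctuation, and the
# physiological clipping range.
.SIM_SIGNALS <- data.frame(
  signal_id = c("SBP", "CVP", "HR", "SpO2", "dPmx", "PCCI", "PPV", "SVI",
                "SVRI", "SVV",
                "CFI", "ELWI", "GEDI", "GEF", "ITBI", "PVPI"),
  baseline_mean = c(110, 7, 80, 98, 900, 3.5, 9, 42, 1900, 9,
                    4.5, 8, 700, 25, 900, 2),
  baseline_sd = c(15, 2.5, 10, 1, 200, 0.7, 3, 8, 400, 3,
                  0.8, 2, 120, 5, 150, 0.5),
  within_sd = c(12, 3, 8, 1.5, 150, 0.5, 3, 6, 250, 3,
                0.4, 1, 60, 2.5, 75, 0.25),
  clip_lo = c(50, 0, 30, 70, 200, 1, 0, 10, 500, 0,
              1, 2, 300, 5, 300, 0.5),
  clip_hi = c(220, 30, 180, 100, 2000, 8, 30, 90, 4000, 30,
              9, 20, 1200, 50, 1800, 5),
  stringsAsFactors = FALSE
)

#' Per-signal simulation defaults
#'
#' @return data.frame of the default baseline mean/SD (between patients),
#'   within-surgery AR(1) marginal SD and clipping range per signal.
#' @export
sim_signal_defaults <- function() .SIM_SIGNALS

#' Simulation configuration
#'
#' Collects all knobs of the synthetic cohort generator. Surgery durations
#' are normal (mean/SD in minutes) truncated below; waveforms are
#' stationary AR(1) fluctuations around a patient-specific baseline, at a
#' fixed sampling interval, clipped to physiological ranges; intermittent
#' indices are emitted every `intermittent_interval_min`. Outcomes are
#' Bernoulli draws from a logistic link on named features, with the
#' intercept tuned so the cohort's expected prevalence hits
#' `prevalence`.
#'
#' @param n_patients Cohort size (default 62).
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @param duration_mean,duration_sd,duration_floor Surgery duration
#'   distribution, minutes (default 420/90, truncated at 240).
#' @param sample_interval_s Sampling interval of continuous signals,
#'   seconds (default 10).
#' @param ar1 Lag-1 autocorrelation of the within-surgery fluctuation, in
#'   `[0, 1)` (default 0.97 at the 10 s interval, i.e. a fluctuation
#'   timescale of minutes, so threshold crossings are sustained rather
#'   than white noise).
#' @param signals Signals to simulate (default: all 16 registry signals).
#' @param intermittent_interval_min Minutes between intermittent-index
#'   updates (default 30).
#' @param outcome_models Named list (`mortality`, `arf`) of named
#'   coefficient vectors (true log-odds per original feature unit) over
#'   features the simulator produces.
#' @param prevalence Named target prevalences in `(0, 0.5]` for the two
#'   outcomes.
#' @param p_missing_preop,p_truncate_waveform,p_missing_product,p_missing_outcome
#'   Per-record probabilities used by [inject_missingness()] (defaults 0).
#' @param within_sd Optional named vector overriding the per-signal AR(1)
#'   marginal SD defaults of [sim_signal_defaults()].
#' @inheritParams hd_signals
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 62, seed = 1,
                       duration_mean = 420, duration_sd = 90,
                       duration_floor = 240,
                       sample_interval_s = 10, ar1 = 0.97,
                       signals = .SIGNALS$signal_id,
                       intermittent_interval_min = 30,
                       outcome_models = list(
                         mortality = c(area_cvp_gt_5 = 0.0015,
                                       vol_whole_blood = 0.05),
                         arf = c(creatinine = 1.0, area_cvp_gt_5 = 0.0012)),
                       prevalence = c(mortality = 0.18, arf = 0.21),
                       p_missing_preop = 0, p_truncate_waveform = 0,
                       p_missing_product = 0, p_missing_outcome = 0,
                       within_sd = NULL,
                       svi_direction = c("below", "above")) {
  stopifnot(n_patients >= 1, ar1 >= 0, ar1 < 1,
            all(prevalence > 0), all(prevalence <= 0.5),
            duration_floor > 0, sample_interval_s > 0)
  unknown <- setdiff(signals, .SIGNALS$signal_id)
  if (length(unknown)) {
    stop("unknown signal(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  structure(list(
    n_patients = n_patients, seed = seed,
    duration_mean = duration_mean, duration_sd = duration_sd,
    duration_floor = duration_floor,
    sample_interval_s = sample_interval_s, ar1 = ar1,
    signals = signals,
    intermittent_interval_min = intermittent_interval_min,
    outcome_models = outcome_models, prevalence = prevalence,
    p_missing_preop = p_missing_preop,
    p_truncate_waveform = p_truncate_waveform,
    p_missing_product = p_missing_product,
    p_missing_outcome = p_missing_outcome,
    within_sd = within_sd,
    svi_direction = match.arg(svi_direction)
  ), class = "sim_config")
}

#' Simulate one hemodynamic waveform
#'
#' Continuous signals: a stationary AR(1) process around `baseline`
#' (marginal SD `within_sd`, lag-1 correlation `ar1`) sampled every
#' `sample_interval_s` seconds for the patient's surgery duration, clipped
#' to the signal's physiological range. Intermittent signals: independent
#' draws every `intermittent_interval_min` minutes.
#'
#' @param signal_id Signal identifier.
#' @param baseline Patient-specific baseline level, signal units.
#' @param duration_min Surgery duration in minutes.
#' @param config A [sim_config()] (sampling interval, AR(1) parameters).
#' @param within_sd Marginal SD of the fluctuation; default from
#'   [sim_signal_defaults()] or the config override.
#' @return A [waveform_signal()]. Uses the current RNG stream; seed
#'   management is the caller's job (see [simulate_cohort()]).
#' @export
simulate_waveform <- function(signal_id, baseline, duration_min,
                              config = sim_config(), within_sd = NULL) {
  row <- .SIM_SIGNALS[.SIM_SIGNALS$signal_id == signal_id, , drop = FALSE]
  if (nrow(row) != 1L) stop("unknown signal: ", signal_id, call. = FALSE)
  sd_w <- within_sd %||% unname(config$within_sd[signal_id]) %||%
    row$within_sd
  if (is.na(sd_w)) sd_w <- row$within_sd
  kind <- .SIGNALS$kind[.SIGNALS$signal_id == signal_id]
  if (kind == "continuous") {
    dt <- config$sample_interval_s
    n <- max(2L, floor(duration_min * 60 / dt))
    times <- seq(0, by = dt, length.out = n)
    rho <- config$ar1
    if (sd_w == 0) {
      e <- rep(0, n)
    } else {
      innov <- stats::rnorm(n, 0, sd_w * sqrt(1 - rho^2))
      e <- as.numeric(stats::filter(innov, rho, method = "recursive",
                                    init = stats::rnorm(1, 0, sd_w)))
    }
    values <- pmin(pmax(baseline + e, row$clip_lo), row$clip_hi)
  } else {
    step_s <- config$intermittent_interval_min * 60
    times <- seq(0, duration_min * 60 - 1e-9, by = step_s)
    values <- pmin(pmax(stats::rnorm(length(times), baseline, sd_w),
                        row$clip_lo), row$clip_hi)
  }
  waveform_signal(signal_id, times, values)
}

# Preoperative feature generator. Correlated laboratory values come from a
# Gaussian copula (MELD positively correlated with INR, bilirubins and
# creatinine, negatively with albumin) so that subset selection faces
# realistic multicollinearity; demographics and comorbidities are
# independent draws with cohort-plausible rates.
.LAB_CORR <- local({
  labs <- c("meld", "inr", "total_bilirubin", "direct_bilirubin",
            "creatinine", "albumin")
  r <- diag(6)
  dimnames(r) <- list(labs, labs)
  set <- function(r, a, b, v) {
    r[a, b] <- v
    r[b, a] <- v
    r
  }
  r <- set(r, "meld", "inr", 0.60)
  r <- set(r, "meld", "total_bilirubin", 0.50)
  r <- set(r, "meld", "direct_bilirubin", 0.40)
  r <- set(r, "meld", "creatinine", 0.50)
  r <- set(r, "meld", "albumin", -0.30)
  r <- set(r, "inr", "total_bilirubin", 0.40)
  r <- set(r, "inr", "direct_bilirubin", 0.30)
  r <- set(r, "inr", "creatinine", 0.20)
  r <- set(r, "inr", "albumin", -0.20)
  r <- set(r, "total_bilirubin", "direct_bilirubin", 0.80)
  r <- set(r, "total_bilirubin", "creatinine", 0.20)
  r <- set(r, "total_bilirubin", "albumin", -0.20)
  r <- set(r, "direct_bilirubin", "creatinine", 0.15)
  r <- set(r, "direct_bilirubin", "albumin", -0.15)
  r <- set(r, "creatinine", "albumin", -0.10)
  r
})

.simulate_preop <- function(n) {
  z <- rmvnorm_chol(n, .LAB_CORR)
  u <- stats::pnorm(z)
  labs <- cbind(
    meld = pmin(pmax(stats::qlnorm(u[, 1], log(17), 0.40), 6), 40),
    inr = stats::qlnorm(u[, 2], log(1.5), 0.25),
    total_bilirubin = stats::qlnorm(u[, 3], log(1.5), 0.75),
    direct_bilirubin = stats::qlnorm(u[, 4], log(1.1), 0.80),
    creatinine = stats::qlnorm(u[, 5], log(0.9), 0.35),
    albumin = pmin(pmax(stats::qnorm(u[, 6], 3.15, 0.5), 1.5), 5))
  cbind(labs,
        age = pmin(pmax(round(stats::rnorm(n, 56, 8)), 18), 75),
        male = stats::rbinom(n, 1, 0.74),
        bmi = pmin(pmax(stats::rnorm(n, 25.5, 3.5), 15), 45),
        diabetes = stats::rbinom(n, 1, 0.24),
        hypertension = stats::rbinom(n, 1, 0.30),
        smoking = stats::rbinom(n, 1, 0.27),
        asa_class = sample(1:4, n, replace = TRUE,
                           prob = c(0.01, 0.09, 0.77, 0.13)),
        piggyback = stats::rbinom(n, 1, 0.39),
        marginal_donor = stats::rbinom(n, 1, 0.45))
}

.simulate_nonhemo <- function(n, durations) {
  cbind(
    vol_whole_blood = stats::rgamma(n, shape = 1.3, scale = 15 / 1.3),
    vol_ffp = stats::rgamma(n, shape = 1.3, scale = 12 / 1.3),
    vol_platelets = stats::rgamma(n, shape = 0.8, scale = 3 / 0.8),
    vol_rbc_auto = stats::rgamma(n, shape = 1.0, scale = 8),
    surgery_duration_min = durations)
}

#' Simulate a synthetic cohort with known ground truth
#'
#' Draws a full cohort: correlated preoperative features, blood-product
#' volumes, truncated-normal surgery durations, AR(1) waveforms per signal
#' around patient-specific baselines, and binary outcomes from a logistic
#' link on the configured features. The outcome-model intercept is tuned
#' by root finding so that the cohort's expected prevalence (mean of the
#' per-patient outcome probabilities over the realized feature draws)
#' equals the configured target. Fully reproducible from `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list with `records` (named list of [patient_record()]s) and
#'   `truth` (class `ground_truth`): per-outcome data.frames of linear
#'   predictor, true probability and drawn label; the true coefficients
#'   and tuned intercepts; and the realized feature matrix.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, .simulate_cohort_impl(config))
}

.simulate_cohort_impl <- function(config) {
  n <- config$n_patients
  ids <- sprintf("P%04d", seq_len(n))
  preop <- .simulate_preop(n)
  durations <- pmax(stats::rnorm(n, config$duration_mean,
                                 config$duration_sd), config$duration_floor)
  nonhemo <- .simulate_nonhemo(n, durations)

  sim_sig <- .SIM_SIGNALS[.SIM_SIGNALS$signal_id %in% config$signals, ,
                          drop = FALSE]
  baselines <- sapply(seq_len(nrow(sim_sig)), function(j) {
    pmin(pmax(stats::rnorm(n, sim_sig$baseline_mean[j],
                           sim_sig$baseline_sd[j]),
              sim_sig$clip_lo[j]), sim_sig$clip_hi[j])
  })
  if (nrow(sim_sig)) colnames(baselines) <- sim_sig$signal_id

  records <- lapply(seq_len(n), function(i) {
    wfs <- list()
    for (sid in sim_sig$signal_id) {
      wfs[[sid]] <- simulate_waveform(sid, baselines[i, sid], durations[i],
                                      config = config)
    }
    patient_record(ids[i], preop = preop[i, ], nonhemo = nonhemo[i, ],
                   outcomes = c(mortality = NA, arf = NA), waveforms = wfs)
  })
  names(records) <- ids

  groups <- c("preoperative",
              if (length(config$signals)) "hemodynamic",
              "nonhemodynamic")
  fm <- build_feature_matrix(records, groups = groups,
                             signals = if (length(config$signals))
                               config$signals else NULL,
                             svi_direction = config$svi_direction)

  truth <- list(coefficients = config$outcome_models,
                intercepts = numeric(), outcomes = list(), features = fm)
  for (oc in names(config$outcome_models)) {
    beta <- config$outcome_models[[oc]]
    if (length(beta)) {
      missing_feat <- setdiff(names(beta), colnames(fm))
      if (length(missing_feat)) {
        stop("outcome model for ", oc, " references feature(s) the ",
             "simulator did not produce: ",
             paste(missing_feat, collapse = ", "), call. = FALSE)
      }
      lp <- drop(fm[, names(beta), drop = FALSE] %*% beta)
    } else {
      lp <- rep(0, n)
    }
    target <- config$prevalence[[oc]]
    f <- function(b) mean(stats::plogis(b + lp)) - target
    if (f(-40) > 0 || f(40) < 0) {
      stop("prevalence target ", target, " unreachable for outcome ", oc,
           " under the configured coefficients", call. = FALSE)
    }
    b0 <- stats::uniroot(f, c(-40, 40), tol = 1e-10)$root
    prob <- stats::plogis(b0 + lp)
    label <- stats::rbinom(n, 1, prob)
    for (i in seq_len(n)) records[[i]]$outcomes[[oc]] <- label[i]
    truth$intercepts[[oc]] <- b0
    truth$outcomes[[oc]] <- data.frame(patient_id = ids, eta = b0 + lp,
                                       prob = prob, label = label,
                                       stringsAsFactors = FALSE)
  }
  class(truth) <- "ground_truth"
  list(records = records, truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth>\n")
  for (oc in names(x$outcomes)) {
    cat(sprintf("  %s: intercept %.3f, prevalence %.3f, coefficients: %s\n",
                oc, x$intercepts[[oc]], mean(x$outcomes[[oc]]$label),
                paste(names(x$coefficients[[oc]]), collapse = ", ")))
  }
  invisible(x)
}

#' Serialize ground truth for test harnesses
#'
#' @param truth A `ground_truth` object.
#' @param path Output CSV path (long format: outcome, patient_id, eta,
#'   prob, label).
#' @return Invisibly, `path`.
#' @export
write_ground_truth <- function(truth, path) {
  long <- do.call(rbind, lapply(names(truth$outcomes), function(oc) {
    cbind(outcome = oc, truth$outcomes[[oc]])
  }))
  data.table::fwrite(long, path)
  invisible(path)
}

#' Inject missingness into a simulated cohort
#'
#' Degrades records completely at random, emulating data-collection
#' failures: with the configured per-record probabilities, one random
#' preoperative cell is deleted, one random continuous waveform is
#' truncated below the 180-minute inclusion threshold (to a uniform 30-170
#' minutes), one random blood-product volume is deleted, or one outcome
#' label is deleted.
#'
#' @param records Named list of [patient_record()]s.
#' @param config A [sim_config()] carrying the dropout probabilities.
#' @param seed Seed for this operation's RNG stream; default derived from
#'   `config$seed`.
#' @return The degraded record list.
#' @export
inject_missingness <- function(records, config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  records <- .as_record_list(records)
  seed <- seed %||% derive_seed(config$seed, "missingness")
  with_seed(seed, {
    for (i in seq_along(records)) {
      r <- records[[i]]
      if (stats::runif(1) < config$p_missing_preop) {
        f <- sample(.PREOP_FEATURES, 1)
        r$preop[[f]] <- NA_real_
      }
      if (stats::runif(1) < config$p_truncate_waveform) {
        cont <- names(r$waveforms)[vapply(r$waveforms, `[[`, character(1),
                                          "kind") == "continuous"]
        if (length(cont)) {
          sid <- if (length(cont) == 1L) cont else sample(cont, 1)
          w <- r$waveforms[[sid]]
          keep_min <- stats::runif(1, 30, 170)
          keep <- w$times < keep_min * 60
          if (sum(keep) < 1L) keep[1L] <- TRUE
          r$waveforms[[sid]] <- waveform_signal(sid, w$times[keep],
                                                w$values[keep])
        }
      }
      if (stats::runif(1) < config$p_missing_product) {
        f <- sample(.VOLUME_FEATURES, 1)
        r$nonhemo[[f]] <- NA_real_
      }
      if (stats::runif(1) < config$p_missing_outcome) {
        oc <- sample(.OUTCOMES, 1)
        r$outcomes[[oc]] <- NA_real_
      }
      records[[i]] <- r
    }
    records
  })
}
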