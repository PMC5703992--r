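# In-code fixtures: small records with constant waveforms whose features are
# known exactly, plus convenience constructors.

make_wave <- function(signal_id, values, dt = 10, t0 = 0) {
  waveform_signal(signal_id, seq(t0, by = dt, length.out = length(values)),
                  values)
}

# Constant-level signal spanning `minutes` of recording (n = minutes*60/dt
# samples, so covered time including the median-interval tail is exactly
# `minutes`).
const_wave <- function(signal_id, level, minutes, dt = 10) {
  make_wave(signal_id, rep(level, minutes * 60 / dt), dt = dt)
}

default_preop <- function() {
  c(age = 56, marginal_donor = 1, inr = 1.5, direct_bilirubin = 1.1,
    total_bilirubin = 1.5, albumin = 3.2, creatinine = 0.9, meld = 17,
    piggyback = 0, male = 1, diabetes = 0, hypertension = 0, smoking = 0,
    asa_class = 3, bmi = 26)
}

default_nonhemo <- function() {
  c(vol_whole_blood = 15, vol_ffp = 12, vol_platelets = 3, vol_rbc_auto = 8,
    surgery_duration_min = 420)
}

# A fully complete record: every signal constant at its simulation baseline
# for `minutes` of recording (dt 30 s keeps fixtures small).
make_record <- function(id, minutes = 200, preop = default_preop(),
                        nonhemo = default_nonhemo(),
                        outcomes = c(mortality = 0, arf = 0),
                        waveform_overrides = list()) {
  defs <- sim_signal_defaults()
  wfs <- lapply(seq_len(nrow(defs)), function(i) {
    sid <- defs$signal_id[i]
    if (!is.null(waveform_overrides[[sid]])) {
      return(waveform_overrides[[sid]])
    }
    if (hd_signals()$kind[i] == "continuous") {
      const_wave(sid, defs$baseline_mean[i], minutes, dt = 30)
    } else {
      make_wave(sid, rep(defs$baseline_mean[i], max(1, minutes %/% 30)),
                dt = 1800)
    }
  })
  names(wfs) <- defs$signal_id
  patient_record(id, preop = preop, nonhemo = nonhemo, outcomes = outcomes,
                 waveforms = wfs)
}

# Independent brute-force AUC oracle: explicit loop over all (case, control)
# pairs, ties counted one half.
auc_pair_counting <- function(scores, labels) {
  cases <- scores[labels == 1]
  ctrls <- scores[labels == 0]
  tot <- 0
  for (a in cases) {
    for (b in ctrls) {
      tot <- tot + (a > b) + 0.5 * (a == b)
    }
  }
  tot / (length(cases) * length(ctrls))
}

# Independent penalized-logistic oracle via general-purpose optimisation.
optim_logistic <- function(x, y, lambda = 0) {
  X <- cbind(1, as.matrix(x))
  negll <- function(beta) {
    eta <- pmin(pmax(drop(X %*% beta), -30), 30)
    -sum(y * eta - log1p(exp(eta))) + lambda * sum(beta[-1]^2) / 2
  }
  stats::optim(rep(0, ncol(X)), negll, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))$par
}
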