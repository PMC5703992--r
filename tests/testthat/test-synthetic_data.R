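test_that("degenerate AR(1) settings give a constant series at baseline", {
  cfg <- sim_config(seed = 1, within_sd = c(CVP = 0))
  set.seed(1)
  w <- simulate_waveform("CVP", baseline = 8, duration_min = 60,
                         config = cfg)
  expect_true(all(w$values == 8))
  expect_equal(length(w$times), 360)
  expect_equal(diff(w$times), rep(10, 359))
})

test_that("simulated waveforms carry the configured lag-1 autocorrelation", {
  # SVRI sits far from its clipping bounds, so clipping cannot distort the
  # autocorrelation estimate
  cfg <- sim_config(seed = 1, ar1 = 0.97)
  set.seed(202)
  w <- simulate_waveform("SVRI", baseline = 1900,
                         duration_min = 1e5 * 10 / 60, config = cfg)
  expect_gte(length(w$values), 1e5)
  r1 <- cor(w$values[-1], w$values[-length(w$values)])
  expect_equal(r1, 0.97, tolerance = 0.02)
})

test_that("exposure area of a simulated signal matches the clipped-normal
           expectation", {
  # CVP ~ AR(1) around 8 with marginal SD 3, threshold above 5:
  # E[max(0, X - 5)] = 3*pnorm(1) + 3*dnorm(1) per minute
  cfg <- sim_config(seed = 1, ar1 = 0.9, within_sd = c(CVP = 3))
  set.seed(203)
  w <- simulate_waveform("CVP", baseline = 8, duration_min = 3000,
                         config = cfg)
  per_min <- 3 * pnorm(1) + 3 * dnorm(1)
  covered <- length(w$values) * 10 / 60
  area <- extract_exposure_area(w)
  expect_equal(area / covered, per_min, tolerance = 0.08)
})

test_that("intermittent indices are emitted on the slow schedule", {
  cfg <- sim_config(seed = 1)
  set.seed(204)
  w <- simulate_waveform("CFI", baseline = 4.5, duration_min = 400,
                         config = cfg)
  expect_equal(w$kind, "intermittent")
  expect_equal(length(w$times), ceiling(400 / 30))
  expect_equal(diff(w$times), rep(1800, length(w$times) - 1))
})

test_that("with no feature effects the prevalence target is hit", {
  cfg <- sim_config(n_patients = 10000, seed = 5, signals = character(),
                    outcome_models = list(mortality =
                                            setNames(numeric(), character())),
                    prevalence = c(mortality = 0.2))
  sim <- simulate_cohort(cfg)
  labels <- sim$truth$outcomes$mortality$label
  expect_equal(mean(labels), 0.2, tolerance = 0.05)
  expect_lt(abs(mean(labels) - 0.2), 0.012)  # binomial 3-sigma at n = 1e4
  expect_equal(mean(sim$truth$outcomes$mortality$prob), 0.2,
               tolerance = 1e-6)
})

test_that("cohorts are reproducible from the seed and differ across seeds", {
  cfg <- function(seed) {
    sim_config(n_patients = 8, seed = seed, signals = c("CVP", "SVI"),
               duration_mean = 300,
               outcome_models = list(mortality = c(vol_whole_blood = 0.05)))
  }
  s1 <- simulate_cohort(cfg(7))
  s2 <- simulate_cohort(cfg(7))
  s3 <- simulate_cohort(cfg(8))
  expect_identical(s1$truth$features, s2$truth$features)
  expect_identical(s1$truth$outcomes$mortality$label,
                   s2$truth$outcomes$mortality$label)
  expect_false(identical(s1$truth$features, s3$truth$features))

  # byte-identical files on rerun
  p1 <- tempfile(fileext = ".csv")
  w1 <- tempfile(fileext = ".csv")
  p2 <- tempfile(fileext = ".csv")
  w2 <- tempfile(fileext = ".csv")
  write_cohort(s1$records, p1, w1)
  write_cohort(s2$records, p2, w2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(readLines(w1), readLines(w2))
})

test_that("simulate -> write -> load -> extract returns the stored truth", {
  cfg <- sim_config(n_patients = 6, seed = 9, signals = c("CVP", "SVI"),
                    duration_mean = 300,
                    within_sd = c(CVP = 0),  # constant signal: exact match
                    outcome_models = list(mortality = c(med_cvp = 0.2)))
  sim <- simulate_cohort(cfg)
  cp <- tempfile(fileext = ".csv")
  wp <- tempfile(fileext = ".csv")
  write_cohort(sim$records, cp, wp)
  back <- load_cohort(cp, wp)
  fm <- build_feature_matrix(back, signals = c("CVP", "SVI"))
  expect_equal(unclass(fm), unclass(sim$truth$features), tolerance = 1e-12)
  # constant CVP: median equals the patient baseline exactly, MAD is zero
  expect_equal(unname(fm[, "mad_cvp"]), rep(0, 6))
})

test_that("missingness injection degrades records as configured", {
  base_cfg <- sim_config(n_patients = 10, seed = 12, signals = c("CVP"),
                         duration_mean = 300,
                         outcome_models = list(mortality =
                                                 c(vol_whole_blood = 0.05)))
  sim <- simulate_cohort(base_cfg)

  # all probabilities zero: records unchanged
  same <- inject_missingness(sim$records, base_cfg)
  expect_identical(same, sim$records)

  # truncation probability 1: every record loses the 180-minute rule
  cfg_tr <- sim_config(n_patients = 10, seed = 12, signals = c("CVP"),
                       duration_mean = 300, p_truncate_waveform = 1,
                       outcome_models = list(mortality =
                                               c(vol_whole_blood = 0.05)))
  broken <- inject_missingness(sim$records, cfg_tr)
  expect_error(apply_inclusion_filters(broken, "mortality",
                                       required_signals = "CVP"),
               "no records pass")
})

test_that("dropout probabilities tuned to the cohort's missingness pattern
           reproduce its exclusion rate", {
  # per-record event probabilities 10/101 (preoperative), 23/101 (waveform),
  # 14/101 (blood product), 1/101 (outcome; halved for one outcome since the
  # deleted label is drawn at random) give an analytic exclusion probability
  p <- c(10, 23, 14) / 101
  p_out <- 1 / 101 / 2
  analytic <- 1 - prod(1 - p) * (1 - p_out)
  expect_lt(abs(analytic - 39 / 101), 0.05)

  n_rep <- 60
  rates <- vapply(seq_len(n_rep), function(i) {
    cfg <- sim_config(n_patients = 101, seed = 1000 + i,
                      signals = c("CVP", "SVI"), sample_interval_s = 60,
                      p_missing_preop = p[1], p_truncate_waveform = p[2],
                      p_missing_product = p[3], p_missing_outcome = 1 / 101,
                      outcome_models = list(mortality =
                                              c(vol_whole_blood = 0.05)))
    sim <- simulate_cohort(cfg)
    degraded <- inject_missingness(sim$records, cfg)
    f <- apply_inclusion_filters(degraded, "mortality",
                                 required_signals = c("CVP", "SVI"))
    nrow(f$exclusions) / 101
  }, numeric(1))
  # SE of the mean rate over 60 cohorts of 101 is about 0.006
  expect_equal(mean(rates), analytic, tolerance = 0.03)
})

test_that("unreachable prevalence and unknown model features error", {
  cfg <- sim_config(n_patients = 20, seed = 3, signals = character(),
                    outcome_models = list(mortality = c(nonexistent = 1)))
  expect_error(simulate_cohort(cfg), "nonexistent")
})
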