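test_that("median follows the sample-median convention", {
  expect_equal(extract_median(make_wave("HR", c(3, 1, 2))), 2)
  expect_equal(extract_median(make_wave("HR", c(1, 2, 3, 4))), 2.5)
  # large simulated series against a sort-based oracle
  set.seed(41)
  v <- rnorm(10000, 80, 10)
  s <- sort(v)
  expect_equal(extract_median(make_wave("HR", v)), (s[5000] + s[5001]) / 2)
  expect_error(extract_median(waveform_signal("HR", numeric(), numeric())),
               "empty")
})

test_that("MAD is the raw median absolute deviation, continuous-only", {
  expect_equal(extract_mad(const_wave("CVP", 7, 10)), 0)
  expect_equal(extract_mad(make_wave("CVP", c(1, 1, 2, 2, 4, 6, 9))), 1)
  # translation invariance
  set.seed(42)
  for (rep in 1:10) {
    v <- rnorm(50, 100, 20)
    shift <- runif(1, -50, 50)
    expect_equal(extract_mad(make_wave("SBP", v + shift)),
                 extract_mad(make_wave("SBP", v)))
  }
  # no 1.4826 consistency factor
  v <- c(10, 12, 15, 20, 30)
  expect_equal(extract_mad(make_wave("SBP", v)),
               median(abs(v - median(v))))
  expect_error(extract_mad(make_wave("CFI", c(4, 5), dt = 1800)),
               "intermittent")
})

test_that("exposure area integrates harmful-side excursions only", {
  # boundary contributes nothing
  expect_equal(extract_exposure_area(const_wave("CVP", 5, 60)), 0)
  # safe side contributes nothing
  expect_equal(extract_exposure_area(const_wave("SpO2", 98, 60)), 0)
  # rectangle: CVP constant 8 for 100 min, threshold above 5
  expect_equal(extract_exposure_area(const_wave("CVP", 8, 100)), 300,
               tolerance = 1e-12)
  # direction below: SBP constant 90 for 30 min, threshold below 100
  expect_equal(extract_exposure_area(const_wave("SBP", 90, 30)), 300,
               tolerance = 1e-12)
})

test_that("exposure area matches a literal per-sample summation oracle", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(20:200, 1)
    times <- cumsum(runif(n, 2, 120))  # irregular, some gaps beyond the cap
    values <- rnorm(n, 6, 3)
    w <- waveform_signal("CVP", times, values)
    spec <- threshold_spec("CVP")
    cap <- 60
    oracle <- 0
    gaps <- diff(times)
    tail_dt <- min(median(gaps), cap)
    for (i in seq_len(n)) {
      dt <- if (i < n) min(times[i + 1] - times[i], cap) else tail_dt
      oracle <- oracle + max(0, values[i] - spec$threshold) * dt / 60
    }
    expect_equal(extract_exposure_area(w, max_gap_s = cap), oracle)
  }
})

test_that("gap capping bounds the contribution of dropouts", {
  # one 10-minute dropout while harmful: only 60 s of it accrues area
  t <- c(0, 10, 20, 620, 630)
  w <- waveform_signal("CVP", t, rep(8, 5))
  # capped dts: 10,10,60,10; tail = median(10,10,600,10)=10
  expect_equal(extract_exposure_area(w), 3 * (10 + 10 + 60 + 10 + 10) / 60)
  expect_warning(
    extract_exposure_area(waveform_signal("CVP", c(0, 120, 240), rep(8, 3))),
    "gap cap")
})

test_that("appending samples moves the area monotonically", {
  set.seed(8)
  base <- waveform_signal("CVP", seq(0, 990, 10), runif(100, 2, 9))
  a0 <- extract_exposure_area(base)
  harmful <- waveform_signal("CVP", c(base$times, seq(1000, 1190, 10)),
                             c(base$values, runif(20, 6, 12)))
  safe <- waveform_signal("CVP", c(base$times, seq(1000, 1190, 10)),
                          c(base$values, runif(20, 0, 4.5)))
  expect_gt(extract_exposure_area(harmful), a0)
  # tail interval is unchanged (median gap still 10 s), so safe-side
  # appends leave the area exactly as it was
  expect_equal(extract_exposure_area(safe), a0)
})

test_that("trapezoid option stays close to the rectangle rule", {
  set.seed(9)
  w <- waveform_signal("CVP", seq(0, 5990, 10), rnorm(600, 7, 2))
  r <- extract_exposure_area(w)
  tr <- extract_exposure_area(w, rule = "trapezoid")
  expect_gt(tr, 0)
  expect_lt(abs(tr - r) / r, 0.2)
})

test_that("feature matrix has the canonical 56-column layout", {
  recs <- list(make_record("a"), make_record("b"))
  fm <- build_feature_matrix(recs)
  expect_equal(dim(fm), c(2L, 56L))
  expect_identical(colnames(fm), hd_feature_registry()$name)
  expect_identical(rownames(fm), c("a", "b"))
  expect_false(anyNA(fm))

  expect_equal(ncol(build_feature_matrix(recs, "nonhemodynamic")), 5L)
  expect_equal(ncol(build_feature_matrix(recs, "hemodynamic")), 36L)
  tags <- attr(fm, "group_tags")
  expect_equal(unname(table(tags)[c("preoperative", "hemodynamic",
                                    "nonhemodynamic")]),
               c(15L, 36L, 5L), ignore_attr = TRUE)

  # constant waveforms at known levels give exact feature values
  defs <- sim_signal_defaults()
  expect_equal(unname(fm["a", "med_cvp"]),
               defs$baseline_mean[defs$signal_id == "CVP"])
  expect_equal(unname(fm["a", "mad_cvp"]), 0)
  expect_equal(unname(fm["a", "area_cvp_gt_5"]),
               (7 - 5) * 200)  # baseline 7, 200 covered minutes
  expect_equal(unname(fm["a", "vol_whole_blood"]), 15)
})

test_that("feature matrix refuses records violating the inclusion contract", {
  bad <- make_record("x", preop = replace(default_preop(), "meld", NA))
  expect_error(build_feature_matrix(list(bad)), "missing.*meld")
  no_sig <- make_record("y")
  no_sig$waveforms$SVV <- NULL
  expect_error(build_feature_matrix(list(no_sig)), "missing signal SVV")
})

test_that("SVI area direction is configurable", {
  regs <- hd_feature_registry(svi_direction = "below")
  expect_true("area_svi_lt_40" %in% regs$name)
  rega <- hd_feature_registry(svi_direction = "above")
  expect_true("area_svi_gt_40" %in% rega$name)
  rec <- make_record("a", waveform_overrides = list(
    SVI = const_wave("SVI", 35, 200)))
  fm_below <- build_feature_matrix(list(rec), "hemodynamic")
  fm_above <- build_feature_matrix(list(rec), "hemodynamic",
                                   svi_direction = "above")
  expect_equal(unname(fm_below[1, "area_svi_lt_40"]), 5 * 200)
  expect_equal(unname(fm_above[1, "area_svi_gt_40"]), 0)
})
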