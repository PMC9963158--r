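# Crystallization-time determination: IMC exotherms and storage trajectories.

test_that("a single exotherm is found at its generated maximum", {
  ex <- data.frame(time_h = 120, enthalpy_J_g = 45,
                   sigma_rise_h = 6, sigma_fall_h = 12)
  rec <- generate_imc_curve(mse_params(2, 1, 0.1), 15, duration_h = 180,
                            exotherms = ex, seed = 7)
  pk <- detect_exotherm_peaks(rec)
  expect_equal(nrow(pk), 1L)
  expect_lt(abs(pk$time_of_maximum_h - 120), 1 / 60)  # one 60 s interval
  expect_lt(abs(pk$area_J_g / 45 - 1), 0.05)
  expect_lte(pk$prominence_uW_g[1], pk$height_uW_g[1] * 1.001)
})

test_that("a pure relaxation decay yields no peaks; short records error", {
  rec <- generate_imc_curve(mse_params(2, 1, 0.1), 15, duration_h = 180,
                            seed = 99)
  expect_identical(nrow(detect_exotherm_peaks(rec)), 0L)
  short <- generate_imc_curve(mse_params(2, 1, 0.1), 15, duration_h = 1,
                              seed = 98)
  expect_error(detect_exotherm_peaks(short), "minimum window")
})

test_that("detection recall and precision are perfect for clear peaks", {
  set.seed(55)
  hits <- vapply(1:25, function(s) {
    t_true <- runif(1, 20, 50)
    ex <- data.frame(time_h = t_true, enthalpy_J_g = 10,
                     sigma_rise_h = 2, sigma_fall_h = 4)
    rec <- generate_imc_curve(mse_params(2, 1, 0.1), 15, duration_h = 60,
                              exotherms = ex, seed = 5500 + s)
    pk <- detect_exotherm_peaks(rec, refine = FALSE)
    nrow(pk) == 1L && abs(pk$time_of_maximum_h - t_true) < 0.5
  }, logical(1))
  expect_true(all(hits))
})

test_that("pooled-vial double peaks are both resolved at their maxima", {
  ex <- data.frame(time_h = c(29.0, 32.3) * 24, enthalpy_J_g = c(45, 36),
                   sigma_rise_h = 6, sigma_fall_h = 12)
  rec <- generate_imc_curve(mse_params(3.5, 1, 0.1), 15,
                            duration_h = 33 * 24 + 60, exotherms = ex,
                            seed = 12)
  pk <- detect_exotherm_peaks(rec)
  expect_equal(nrow(pk), 2L)
  expect_lt(max(abs(pk$time_of_maximum_h - c(29.0, 32.3) * 24)), 1 / 60)
  # peak-maximum convention and double-peak policies
  expect_equal(as.numeric(imc_crystallization_time(pk, "first")),
               pk$time_of_maximum_h[1])
  expect_equal(as.numeric(imc_crystallization_time(pk, "largest_area")),
               pk$time_of_maximum_h[which.max(pk$area_J_g)])
  expect_equal(as.numeric(imc_crystallization_time(pk, "mean_of_maxima")),
               mean(pk$time_of_maximum_h))
  expect_true(is.na(imc_crystallization_time(pk[0, , drop = FALSE])))
})

test_that("storage rule interpolates the enthalpy-fraction crossing", {
  rec <- storage_record("s1", 25, 0:3,
                        data.frame(cryst_enthalpy_J_g = c(50, 50, 24, 0)))
  expect_equal(as.numeric(storage_crystallization_time(rec, theta = 0.5)),
               1 + 25 / 26, tolerance = 1e-12)
  # invariance to uniform enthalpy scaling
  rec2 <- storage_record("s1", 25, 0:3,
                         data.frame(cryst_enthalpy_J_g = 7 * c(50, 50, 24, 0)))
  expect_equal(as.numeric(storage_crystallization_time(rec2, theta = 0.5)),
               1 + 25 / 26, tolerance = 1e-12)
})

test_that("storage rule handles degenerate trajectories", {
  const <- storage_record("s", 25, c(0, 7, 14),
                          data.frame(cryst_enthalpy_J_g = c(50, 50, 49)))
  expect_true(is.na(storage_crystallization_time(const)))   # still amorphous
  done <- storage_record("s", 25, c(0, 7),
                         data.frame(cryst_enthalpy_J_g = c(0, 0)))
  expect_identical(as.numeric(storage_crystallization_time(done)), 0)
  miss <- storage_record("s", 25, c(0, 7),
                         data.frame(cryst_enthalpy_J_g = c(NA, 10)))
  expect_error(storage_crystallization_time(miss), "week-0")
  one <- storage_record("s", 25, 0, data.frame(cryst_enthalpy_J_g = 50))
  expect_error(storage_crystallization_time(one), "at least two")
})

test_that("the onset-drop rule interpolates the onset trajectory", {
  rec <- storage_record("s", 25, c(0, 7, 14, 21),
                        data.frame(cryst_enthalpy_J_g = c(50, 45, 40, 35),
                                   cryst_onset_C = c(85, 84, 78, 70)))
  ct <- storage_crystallization_time(rec, rule = "onset_drop", delta_T = 5)
  expect_equal(as.numeric(ct), 7 + (84 - 80) / (84 - 78) * 7, tolerance = 1e-12)
})

test_that("earlier true crystallization gives strictly earlier derived times", {
  t_true <- c(20, 35, 50, 65, 80)
  times <- 7 * (0:16)
  set.seed(9)
  derived <- vapply(t_true, function(tc) {
    e <- 50 * (1 - stats::plogis((times - tc) / 3.5)) *
      exp(rnorm(length(times), 0, 0.01))
    rec <- storage_record("s", 25, times, data.frame(cryst_enthalpy_J_g = e))
    as.numeric(storage_crystallization_time(rec))
  }, numeric(1))
  expect_true(all(diff(derived) > 0))
  expect_lt(max(abs(derived - t_true)), 2)
})

test_that("storage round trip through generated thermograms recovers t_c", {
  tr <- generate_storage_trajectory(tg = 60.21, delta_cp = 0.5,
                                    t_c_days = 45, times_days = 7 * (0:10),
                                    seed = 77)
  wk <- weekly_features(tr$thermograms, tr$times_days)
  rec <- storage_record("rt", 25, tr$times_days, wk)
  ct <- storage_crystallization_time(rec)
  expect_lt(abs(as.numeric(ct) - 45), 2)
  # onset trajectory decreases with storage age (ongoing crystallization)
  on <- wk$cryst_onset_C[!is.na(wk$cryst_onset_C)]
  expect_lt(stats::cor(seq_along(on), on), 0)
})
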