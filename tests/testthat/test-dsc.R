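# DSC feature extraction: glass transition and crystallization peak.

test_that("a clean synthetic step is recovered at the generator truth", {
  tg <- generate_dsc_thermogram(60.21, 0.60, cryst_enthalpy_J_g = 0,
                                snr = 1e9, seed = 1)
  gt <- extract_glass_transition(tg)
  expect_equal(gt$tg_midpoint, 60.21, tolerance = 0.05 / 60.21)
  expect_equal(gt$delta_cp, 0.60, tolerance = 0.005 / 0.6)
  expect_lte(gt$tg_onset, gt$tg_midpoint)
})

test_that("glass-transition recovery holds across randomized Tg and delta_cp at SNR 50", {
  set.seed(71)
  for (k in 1:8) {
    tg_true <- runif(1, 50, 108)
    dcp_true <- runif(1, 0.3, 0.8)
    th <- generate_dsc_thermogram(tg_true, dcp_true, cryst_enthalpy_J_g = 0,
                                  snr = 50, seed = 7000 + k)
    gt <- extract_glass_transition(th)
    expect_lt(abs(gt$tg_midpoint - tg_true), 0.2)
    expect_lt(abs(gt$delta_cp / dcp_true - 1), 0.03)
  }
})

test_that("a flat baseline has no glass transition", {
  tt <- seq(25, 160, by = 1 / 30)
  set.seed(8)
  flat <- dsc_thermogram(tt, 0.002 + rnorm(length(tt), 0, 1e-5),
                         0.002 + rnorm(length(tt), 0, 1e-5))
  expect_error(extract_glass_transition(flat), "no glass transition found")
})

test_that("crystallization onset and enthalpy are recovered within tolerance", {
  th <- generate_dsc_thermogram(60.21, 0.5, cryst_onset_C = 85,
                                cryst_enthalpy_J_g = 45, seed = 21)
  ce <- extract_crystallization_event(th)
  expect_lt(abs(ce$cryst_onset - 85), 0.5)
  expect_lt(abs(ce$cryst_enthalpy / 45 - 1), 0.02)
  expect_gt(ce$cryst_peak_T, ce$cryst_onset)
})

test_that("no peak means zero enthalpy and absent temperatures", {
  th <- generate_dsc_thermogram(60.21, 0.5, crystallized_fraction = 1,
                                seed = 22)
  ce <- extract_crystallization_event(th)
  expect_identical(ce$cryst_enthalpy, 0)
  expect_true(is.na(ce$cryst_onset))
})

test_that("extracted enthalpy is invariant to heating rate and baseline slope", {
  for (rate in c(2, 4)) {
    th <- generate_dsc_thermogram(60.21, 0.5, cryst_enthalpy_J_g = 45,
                                  heating_rate = rate, seed = 31)
    ce <- extract_crystallization_event(th)
    expect_lt(abs(ce$cryst_enthalpy / 45 - 1), 0.02)
  }
  # add a strong linear slope on top of the signal: area must not change
  th <- generate_dsc_thermogram(60.21, 0.5, cryst_enthalpy_J_g = 45, seed = 32)
  tilted <- dsc_thermogram(th$temperature_C,
                           th$reversing_W_g + 5e-5 * th$temperature_C,
                           th$total_W_g + 5e-5 * th$temperature_C,
                           heating_rate = th$heating_rate)
  ce <- extract_crystallization_event(tilted)
  expect_lt(abs(ce$cryst_enthalpy / 45 - 1), 0.02)
})

test_that("increasing pre-crystallized fraction monotonically lowers enthalpy", {
  fracs <- c(0, 0.25, 0.5, 0.75)
  e <- vapply(seq_along(fracs), function(i) {
    th <- generate_dsc_thermogram(60.21, 0.5, cryst_enthalpy_J_g = 45,
                                  crystallized_fraction = fracs[i],
                                  seed = 40 + i)
    extract_crystallization_event(th)$cryst_enthalpy
  }, numeric(1))
  expect_true(all(diff(e) < 0))
})

test_that("overlapping exotherms warn and return the lowest-temperature peak", {
  th <- generate_dsc_thermogram(60.21, 0.5, cryst_onset_C = 85,
                                cryst_enthalpy_J_g = 45, seed = 51)
  rate_Ks <- th$heating_rate / 60
  second <- 30 * rate_Ks / (2 * sqrt(2 * pi)) *
    exp(-(th$temperature_C - 115)^2 / (2 * 2^2))
  both <- dsc_thermogram(th$temperature_C, th$reversing_W_g,
                         th$total_W_g + second, heating_rate = th$heating_rate)
  expect_warning(ce <- extract_crystallization_event(both), "multiple")
  expect_lt(abs(ce$cryst_peak_T - 89), 1)
})

test_that("thermogram CSV I/O round-trips and validates columns", {
  th <- generate_dsc_thermogram(60.21, 0.5, seed = 61)
  f <- file.path(tempdir(), "dsc.csv")
  write_dsc_csv(th, f)
  back <- read_dsc_csv(f)
  expect_equal(back$reversing_W_g, th$reversing_W_g, tolerance = 1e-7)
  bad <- file.path(tempdir(), "dsc_bad.csv")
  writeLines(c("temperature_C,reversing_W_per_g", "25,0"), bad)
  expect_error(read_dsc_csv(bad), "total_W_per_g")
})
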