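# IMC record handling and the constrained MSE fit.

make_noiseless_record <- function(params = mse_params(2, 1, 0.1),
                                  ctx = thermal_context(25, 60.21, 0.5),
                                  duration = 12) {
  tt <- imc_sampling_grid(duration)
  power_time_series(tt, mse_power(tt, params, ctx))
}

test_that("the standard acquisition scheme yields 1800 + 3960 points", {
  g <- imc_sampling_grid(12)
  expect_length(g, 5760L)
  expect_equal(sum(g <= 1), 1800L)
  expect_equal(diff(g)[1] * 3600, 2, tolerance = 1e-9)
  expect_equal(diff(g)[2000] * 3600, 10, tolerance = 1e-9)
})

test_that("record validation rejects malformed input", {
  expect_error(power_time_series(c(1, 2, 2), c(1, 2, 3)), "strictly increasing")
  expect_error(power_time_series(c(-1, 2), c(1, 2)), ">= 0")
  expect_error(power_time_series(1:3, 1:2), "same length")
})

test_that("preprocess trims by time window and preserves the time origin", {
  rec <- make_noiseless_record()
  same <- preprocess_imc(rec, 0, 12)
  expect_identical(same$times_h, rec$times_h)
  expect_identical(same$power_uW_g, rec$power_uW_g)
  cut <- preprocess_imc(rec, 0.1, 12)
  expect_identical(cut$times_h, rec$times_h[rec$times_h >= 0.1])
  expect_equal(min(cut$times_h), 0.1, tolerance = 1e-3)  # not re-zeroed
  expect_error(preprocess_imc(rec, 13, 14), "no data points")
  expect_error(preprocess_imc(rec, 5, 3), "duration")
})

test_that("noiseless curves are recovered from perturbed starts", {
  ctx <- thermal_context(25, 60.21, 0.5)
  for (true in list(mse_params(2, 1, 0.1), mse_params(3.5, 0.8, 0.4),
                    mse_params(1.5, 0.3, 0.85))) {
    rec <- make_noiseless_record(true, ctx)
    start <- mse_params(1.5 * true$tau0, 1.5 * true$tau1,
                        min(1, 1.5 * true$beta))
    fit <- fit_mse(rec, ctx, start = start)
    expect_true(fit$converged)
    expect_equal(fit$params$tau0, true$tau0, tolerance = 1e-3)
    expect_equal(fit$params$tau1, true$tau1, tolerance = 1e-3)
    expect_equal(fit$params$beta, true$beta, tolerance = 1e-3)
    expect_equal(fit$tau_beta, tau_beta(true), tolerance = 1e-3)
    expect_lte(fit$r2_fit, 1)
  }
})

test_that("fitted parameters always satisfy the constraints", {
  ctx <- thermal_context(25, 60.21, 0.5)
  set.seed(77)
  # adversarial inputs: wrong-shaped decays, offsets, pure noise on a trend
  tt <- imc_sampling_grid(12)[seq(1, 5760, by = 8)]
  adversarial <- list(
    power_time_series(tt, 100 * exp(-tt / 0.05) + rnorm(length(tt), 0, 0.5)),
    power_time_series(tt, 5 + tt * 0.3 + rnorm(length(tt), 0, 0.2)),
    power_time_series(tt, rnorm(length(tt), 2, 1)))
  for (rec in adversarial) {
    fit <- fit_mse(rec, ctx)
    expect_gt(fit$params$tau0, fit$params$tau1)
    expect_gt(fit$params$tau1, 0)
    expect_gt(fit$params$beta, 0)
    expect_lte(fit$params$beta, 1)
  }
})

test_that("noisy recovery keeps median tau_beta error small and scales with noise", {
  ctx <- thermal_context(25, 60.21, 0.5)
  true <- mse_params(2, 1, 0.1)
  tt <- imc_sampling_grid(12)
  p_clean <- mse_power(tt, true, ctx)
  p0 <- mse_power(0, true, ctx)
  errs <- sapply(c(0.005, 0.01, 0.02), function(level) {
    sapply(1:12, function(s) {
      set.seed(1000 + s)   # same seeds across noise levels (paired)
      rec <- power_time_series(tt, p_clean + rnorm(length(tt), 0, level * p0))
      fit <- fit_mse(rec, ctx)
      abs(fit$tau_beta / tau_beta(true) - 1)
    })
  })
  med <- apply(errs, 2, stats::median)
  expect_lt(med[2], 0.05)          # 1% noise: median tau_beta error < 5%
  expect_true(all(diff(med) >= 0)) # error non-decreasing with noise level
})

test_that("degenerate records are flagged, not fitted", {
  ctx <- thermal_context(25, 60.21, 0.5)
  tt <- imc_sampling_grid(2)
  zero <- power_time_series(tt, rep(0, length(tt)))
  fit <- fit_mse(zero, ctx)
  expect_false(fit$converged)
  expect_null(fit$params)
  expect_match(fit$message, "no relaxation signal")
  rep_row <- fit_report(fit)
  expect_false(rep_row$converged)
  expect_true(is.na(rep_row$tau0_h))
  expect_error(fit_mse(power_time_series(1:5 / 10, 5:1), ctx), "too few")
})

test_that("fitting is deterministic: identical inputs give identical parameters", {
  ctx <- thermal_context(25, 60.21, 0.5)
  set.seed(5)
  tt <- imc_sampling_grid(12)
  rec <- power_time_series(tt, mse_power(tt, mse_params(2, 1, 0.1), ctx) +
                             rnorm(length(tt), 0, 1))
  f1 <- fit_mse(rec, ctx)
  f2 <- fit_mse(rec, ctx)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$rss, f2$rss)
})

test_that("IMC CSV round-trips are lossless and errors name the line", {
  rec <- generate_imc_curve(mse_params(2, 1, 0.1), 15, duration_h = 1,
                            noise_sd_uW_g = 0.1, seed = 3,
                            sample_id = "rt")
  f1 <- file.path(tempdir(), "rt1.csv"); f2 <- file.path(tempdir(), "rt2.csv")
  write_imc_csv(rec, f1, time_unit = "s")
  back <- read_imc_csv(f1, time_unit = "s", sample_id = "rt")
  expect_equal(back$times_h, rec$times_h, tolerance = 1e-11)
  expect_equal(back$power_uW_g, rec$power_uW_g, tolerance = 1e-11)
  write_imc_csv(back, f2, time_unit = "s")
  expect_identical(readLines(f1), readLines(f2))
  # explicit-unit contract and malformed input diagnostics
  expect_error(read_imc_csv(f1, time_unit = "h"), "time_h")
  bad <- file.path(tempdir(), "bad.csv")
  writeLines(c("time_s,power_uW_per_g", "2,5", "4,4", "4,3", "6,2"), bad)
  expect_error(read_imc_csv(bad, time_unit = "s"), "line 3")
})
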