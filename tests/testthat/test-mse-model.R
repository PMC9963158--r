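# Closed-form MSE model: survival function, heat flow, amplitude, tau_beta.

test_that("parameter and context validation enforces the model constraints", {
  expect_error(mse_params(1, 2, 0.5), "tau0 > tau1")
  expect_error(mse_params(2, -1, 0.5), "tau1")
  expect_error(mse_params(2, 1, 0), "beta")
  expect_error(mse_params(2, 1, 1.2), "beta")
  expect_s3_class(mse_params(2, 1, 1), "mse_params")   # beta = 1 is allowed
  expect_error(delta_h_r_inf(65, 60.21, 0.5), "above Tg")
  expect_error(delta_h_r_inf(25, 60.21, -0.1), "delta_cp")
  expect_error(relaxation_survival(-1, mse_params(2, 1, 0.5)), "non-negative")
})

test_that("survival function matches its closed form and limits", {
  p <- mse_params(2, 1, 0.1)
  expect_identical(relaxation_survival(0, p), 1)
  # hand evaluation of the closed form at t = 1 h
  expect_equal(relaxation_survival(1, p), exp(-0.5 * 2^(-0.9)),
               tolerance = 1e-12)
  # beta = 1 collapses to a simple exponential in tau0
  p1 <- mse_params(2, 1, 1)
  tt <- c(0.5, 2, 7)
  expect_equal(relaxation_survival(tt, p1), exp(-tt / 2), tolerance = 1e-12)
  expect_equal(relaxation_survival(2, p1), exp(-1), tolerance = 1e-12)
  expect_lt(relaxation_survival(1e16, p), 1e-6)  # beta = 0.1 decays slowly
})

test_that("heat flow matches the prefactor, the beta=1 form, and dHr_inf", {
  expect_equal(mse_power(0, mse_params(1, 0.5, 0.5), ctx = 1), 277.8,
               tolerance = 1e-12)
  expect_equal(mse_power(0, mse_params(1, 0.2, 0.9), ctx = 1), 277.8,
               tolerance = 1e-12)
  # beta = 1: P(t) = 277.8 * (H/tau0) * exp(-t/tau0) exactly
  p1 <- mse_params(1, 0.5, 1)
  tt <- seq(0, 5, by = 0.25)
  expect_equal(mse_power(tt, p1, ctx = 1), 277.8 * exp(-tt), tolerance = 1e-12)
  expect_equal(mse_power(1, p1, ctx = 1), 277.8 / exp(1), tolerance = 1e-12)
  # amplitude arithmetic from glass-transition data
  expect_equal(delta_h_r_inf(25, 60.21, 0.5), 17.605, tolerance = 1e-12)
  expect_equal(delta_h_r_inf(40, 104.46, 0.4), 25.784, tolerance = 1e-12)
  expect_identical(delta_h_r_inf(60.21, 60.21, 0.5), 0)
  ctx <- thermal_context(25, 60.21, 0.5)
  expect_equal(mse_power(0, mse_params(1, 0.5, 0.5), ctx),
               277.8 * 17.605, tolerance = 1e-12)
})

test_that("heat flow is the exact negative derivative of the survival curve", {
  set.seed(401)
  for (k in 1:20) {
    p <- random_params()
    h_amp <- stats::runif(1, 1, 40)
    tt <- stats::runif(100, 0, 5 * p$tau0)
    dt <- 1e-5 * (tt + p$tau1)
    dphi <- (phi_oracle(tt + dt, p$tau0, p$tau1, p$beta) -
             phi_oracle(tt - dt, p$tau0, p$tau1, p$beta)) / (2 * dt)
    expect_lt(max(abs(mse_power(tt, p, h_amp) - (-277.8 * h_amp * dphi)) /
                    mse_power(tt, p, h_amp)), 1e-6)
  }
})

test_that("integrated heat flow returns the full relaxation enthalpy", {
  set.seed(402)
  for (k in 1:50) {
    p <- random_params()
    h_amp <- stats::runif(1, 0.5, 40)
    expect_lt(abs(integrate_power_J_g(p, h_amp) / h_amp - 1), 1e-3)
  }
})

test_that("survival and power are strictly decreasing for all valid beta", {
  tt <- c(seq(0, 2, by = 0.01), seq(2.1, 50, by = 0.1))
  for (beta in c(0.05, 0.1, 0.5, 0.9, 1)) {
    p <- mse_params(2, 1, beta)
    expect_true(all(diff(relaxation_survival(tt, p)) < 0))
    expect_true(all(diff(mse_power(tt, p, 10)) < 0))
  }
})

test_that("long-time behaviour converges to the KWW stretched exponential", {
  set.seed(403)
  for (k in 1:10) {
    p <- random_params()
    t_far <- 100 * p$tau1
    exp_mse <- (t_far / p$tau0) * (1 + t_far / p$tau1)^(p$beta - 1)
    tau_b <- tau_beta(p)                       # tau^beta = tau0 * tau1^(beta-1)
    exp_kww <- t_far^p$beta / (p$tau0 * p$tau1^(p$beta - 1))
    expect_lt(abs(exp_mse / exp_kww - 1), 0.01)
    expect_equal(tau_b, p$tau0 * p$tau1^(p$beta - 1), tolerance = 1e-12)
  }
})

test_that("tau_beta conventions reduce correctly", {
  expect_equal(tau_beta(mse_params(2, 1, 0.37)), 2)         # tau1 = 1 h
  expect_equal(tau_beta(mse_params(3, 0.4, 1)), 3)          # beta = 1
  expect_equal(tau_beta(mse_params(2, 0.5, 0.5)), 2 * 0.5^(-0.5),
               tolerance = 1e-12)
  expect_equal(tau_beta(mse_params(2, 0.5, 0.5), convention = "tau0_beta"),
               sqrt(2), tolerance = 1e-12)
  expect_gt(tau_beta(mse_params(5, 0.2, 0.3)), 0)
})
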