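# Independent closed-form oracles, written directly from the model
# definitions and kept separate from the package implementation paths.

# survival function, written out independently for finite-difference checks
phi_oracle <- function(t, tau0, tau1, beta) {
  exp(-(t / tau0) * (1 + t / tau1)^(beta - 1))
}

# total heat released in J/g by adaptive quadrature of the power curve;
# integrates in log time because small stretch exponents spread the decay
# over many decades
integrate_power_J_g <- function(p, h_amp) {
  t_star <- (30 * p$tau0 * p$tau1^(p$beta - 1))^(1 / p$beta)  # Phi ~ e^-30
  s_max <- log1p(max(t_star, 100 * p$tau0))
  g <- function(s) mse_power(expm1(s), p, h_amp) * exp(s)
  q <- stats::integrate(g, 0, s_max, rel.tol = 1e-9, subdivisions = 1000L)
  q$value * 3.6e-3
}

# random valid MSE parameter set (tau0 > tau1 > 0, 0 < beta <= 1)
random_params <- function() {
  tau1 <- stats::runif(1, 0.05, 5)
  mse_params(tau0 = tau1 * stats::runif(1, 1.2, 10), tau1 = tau1,
             beta = stats::runif(1, 0.05, 1))
}
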