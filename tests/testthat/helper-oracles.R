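# Independent oracles used across the suite.

# Dense-grid trapezoidal evaluation of the fibre-recruitment stress
# integral (brute force; independent of the package's quadrature and
# closed-form paths).
trapezoid_stress_oracle <- function(eps, epsdot, spec, n_nodes = 1e6 + 1) {
  if (eps <= 0) return(0)
  s <- seq(0, eps, length.out = n_nodes)
  f <- dweibull(s, shape = spec$weibull_shape, scale = spec$weibull_scale) *
    (spec$elastic_modulus * (eps - s) + spec$viscosity * epsdot)
  h <- eps / (n_nodes - 1)
  max(h * (sum(f) - 0.5 * (f[1] + f[length(f)])), 0)
}

# Second-order recursion through R's ARMA filter: an independent route
# to u(t) = gain * e(t - d) - beta1 u(t-1) - beta2 u(t-2).
arma_recursion_oracle <- function(e, params, dt) {
  d <- round(params$delay_ms / 1000 / dt)
  ed <- c(rep(0, d), e)[seq_along(e)]
  as.numeric(stats::filter(params$gain * ed,
                           filter = c(-params$beta1, -params$beta2),
                           method = "recursive"))
}

# Pearson r from raw sums (textbook covariance formula).
pearson_sum_oracle <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
}

# Draw a random but feasible summary row within +/- 2 SD of the
# calibrated means.
random_summary_row <- function(cal = cohort_calibration()) {
  vars <- cal$variables
  vals <- cal$means[vars] + runif(length(vars), -2, 2) * cal$sds[vars]
  as.list(vals)
}
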