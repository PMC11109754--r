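aacl <- acl_bundles()[["A-ACL"]]
pacl <- acl_bundles()[["P-ACL"]]

test_that("strain is the relative elongation, with slack allowed", {
  expect_equal(compute_strain(33, 30), 0.10)
  expect_equal(compute_strain(30, 30), 0)
  expect_equal(compute_strain(23.36 * 1.05, 23.36), 0.05)
  expect_lt(compute_strain(28, 30), 0)
  expect_error(compute_strain(30, 0), "positive")
})

test_that("strain rate is exact for constant and linear strain histories", {
  expect_equal(compute_strain_rate(rep(0.07, 50), 0.005), rep(0, 50))
  t <- seq(0, 1, by = 0.005)
  expect_equal(compute_strain_rate(0.2 * t, 0.005), rep(0.2, length(t)),
               tolerance = 1e-12)
  expect_error(compute_strain_rate(0.1, 0.005), "two samples")
})

test_that("strain rate of a sinusoid matches the analytic derivative", {
  dt <- 0.001
  t <- seq(0, 1, by = dt)
  rate <- compute_strain_rate(0.05 * sin(2 * pi * t), dt)
  truth <- 0.05 * 2 * pi * cos(2 * pi * t)
  interior <- 2:(length(t) - 1)
  expect_lt(max(abs(rate[interior] - truth[interior])), 1e-2 * max(abs(truth)))
})

test_that("recruitment density is a proper Weibull density", {
  expect_equal(weibull_recruitment_density(0), 0)
  expect_equal(weibull_recruitment_density(-0.2), 0)
  expect_equal(weibull_recruitment_density(0.3), (4.5 / 0.3) * exp(-1))
  total <- integrate(weibull_recruitment_density, 0, Inf)$value
  expect_equal(total, 1, tolerance = 1e-8)
})

test_that("slack and zero-strain states carry exactly zero stress", {
  expect_identical(nominal_axial_stress(0, 5, aacl), 0)
  expect_identical(nominal_axial_stress(-0.05, 5, aacl), 0)
  dec <- stress_decomposition(-0.01, 3, aacl)
  expect_identical(dec$total, 0)
  expect_identical(dec$elastic, 0)
})

test_that("quadrature stress reproduces frozen dense-grid oracle values", {
  # values pinned from trapezoid_stress_oracle at 1e6 + 1 nodes
  expect_equal(nominal_axial_stress(0.10, 0, aacl), 0.00905396865641,
               tolerance = 1e-9)
  expect_equal(nominal_axial_stress(0.10, 1.0, aacl), 0.151102742993,
               tolerance = 1e-9)
  expect_equal(nominal_axial_stress(0.30, 1.0, aacl), 15.6124402222,
               tolerance = 1e-9)
  expect_equal(nominal_axial_stress(0.20, 2.0, aacl), 6.35094729735,
               tolerance = 1e-9)
})

test_that("analytic and quadrature stress paths agree", {
  eps <- seq(0.02, 0.6, length.out = 15)
  for (ed in c(0, 0.5, 2)) {
    q <- nominal_axial_stress(eps, ed, aacl, method = "quadrature")
    a <- nominal_axial_stress(eps, ed, aacl, method = "analytic")
    expect_equal(q, a, tolerance = 1e-8)
  }
})

test_that("viscous increment equals eta * rate * recruited fraction", {
  for (eps in c(0.1, 0.2, 0.4)) {
    inc <- nominal_axial_stress(eps, 1.0, aacl) -
      nominal_axial_stress(eps, 0, aacl)
    expect_equal(inc, 20 * 1.0 * weibull_recruitment_cdf(eps),
                 tolerance = 1e-8)
  }
  dec <- stress_decomposition(0.2, 2.0, aacl)
  expect_equal(dec$viscous / (20 * 2.0), weibull_recruitment_cdf(0.2),
               tolerance = 1e-8)
  expect_equal(dec$total, dec$elastic + dec$viscous)
})

test_that("stress is strictly increasing in strain at fixed rate", {
  eps <- seq(0.01, 0.8, length.out = 40)
  for (ed in c(0, 1)) {
    sig <- nominal_axial_stress(eps, ed, aacl, method = "analytic")
    expect_true(all(diff(sig) > 0))
  }
})

test_that("negative strain rates reduce stress but never below zero", {
  mild <- nominal_axial_stress(0.3, -0.1, aacl)
  expect_lt(mild, nominal_axial_stress(0.3, 0, aacl))
  expect_gt(mild, 0)
  expect_identical(nominal_axial_stress(0.3, -100, aacl), 0)
})

test_that("force is stress times area, flagged above max isometric force", {
  expect_equal(as.numeric(ligament_force(1.0, aacl)), 20.7)
  expect_equal(as.numeric(ligament_force(0, aacl)), 0)
  f <- ligament_force(82.9, pacl)
  expect_equal(as.numeric(f), 1599.97)
  expect_length(attr(f, "exceeds_max_isometric"), 0)
  f2 <- ligament_force(c(82.9, 83.0), pacl)
  expect_equal(attr(f2, "exceeds_max_isometric"), 2L)
  expect_equal(as.numeric(f2)[2], 1601.9)  # flagged, not clamped
  expect_error(ligament_force(-1, pacl), "non-negative")
})

test_that("total ACL force is the element-wise bundle sum", {
  expect_equal(total_acl_force(c(100, 200), c(50, 50)), c(150, 250))
  expect_equal(total_acl_force(numeric(3), numeric(3)), numeric(3))
  set.seed(11)
  a <- runif(20); b <- runif(20)
  expect_equal(total_acl_force(a, b), total_acl_force(b, a))
  expect_error(total_acl_force(1:3, 1:4), "equal length")
})

test_that("elongation mapping evaluates polynomials and guards its range", {
  flex <- seq(0, 60, by = 5)
  const_map <- list(coefficients = 30, range = c(0, 90))
  expect_equal(acl_elongation_from_knee_flexion(flex, const_map),
               rep(30, length(flex)))
  lin_map <- list(coefficients = c(30, 0.05), range = c(0, 90))
  expect_equal(acl_elongation_from_knee_flexion(flex, lin_map),
               30 + 0.05 * flex)
  expect_error(acl_elongation_from_knee_flexion(100, lin_map), "range")
  expect_error(acl_elongation_from_knee_flexion(30, list(coefficients = 1)),
               "range")
})

test_that("sixth-order material fit recovers exact and noisy polynomials", {
  co <- c(0.4, -1, 2, 0.5, -0.2, 0.1, 3)
  x <- seq(0, 1, length.out = 25)
  y <- drop(outer(x, 0:6, `^`) %*% co)
  fit <- fit_material_polynomial(list(cbind(x, y)))
  expect_equal(fit$coefficients, co, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(fit$sample_count, 1L)
  expect_lt(fit$fit_residual, 1e-10)

  # identical replicate curves: mean equals any single fit
  fit3 <- fit_material_polynomial(replicate(3, cbind(x, y), simplify = FALSE))
  expect_equal(fit3$coefficients, fit$coefficients)

  # noisy curves vs a normal-equations oracle, curve by curve
  set.seed(42)
  curves <- lapply(1:4, function(i) cbind(x, y + rnorm(length(x), sd = 0.01)))
  fitn <- fit_material_polynomial(curves)
  X <- outer(x, 0:6, `^`)
  oracle <- t(vapply(curves, function(cv) {
    drop(solve(crossprod(X), crossprod(X, cv[, 2])))
  }, numeric(7)))
  expect_equal(fitn$coefficients, colMeans(oracle), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_error(fit_material_polynomial(list(cbind(rep(0.5, 9), 1:9))),
               "rank-deficient")
})

test_that("strain-limit report flags passive and junction violations", {
  rep0 <- strain_limit_check(rep(0, 50), aacl)
  expect_length(rep0$passive_violations, 0)
  rep1 <- strain_limit_check(c(0.1, 0.16, 0.12), aacl)
  expect_equal(rep1$passive_violations, 2L)
  ramp <- seq(0, 0.3, length.out = 301)  # crosses 0.15 after index 151
  repr <- strain_limit_check(ramp, aacl)
  expect_equal(min(repr$passive_violations), 152L)
  repj <- strain_limit_check(c(0.01, 0.04, 0.01), aacl,
                             junction_window = c(1, 3))
  expect_true(repj$junction_exceeded)
})

test_that("bundle parameter validation rejects unphysical inputs", {
  expect_error(ligament_bundle("x", -1, 20, 1500), "resting_length")
  expect_error(ligament_bundle("x", 30, 20, 1500, weibull_shape = 0), "Weibull")
  expect_error(ligament_bundle("x", 30, 20, 1500, weibull_location = 0.1),
               "fixed at 0")
  expect_error(ligament_bundle("x", 30, 20, 1500, passive_strain_cap = 1.2),
               "caps")
})
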