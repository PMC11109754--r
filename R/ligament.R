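# Viscoelastic dense-connective-tissue (DCT) model of the ACL.
#
# The ligament is modelled as a bundle of collagen fibres that straighten
# (are "recruited") sequentially as strain increases.  The fraction of
# fibres recruited at strain eps_s follows a two-parameter Weibull
# distribution; each recruited fibre contributes a linear-elastic stress
# K*(eps - eps_s) plus a viscous stress eta*epsdot.  Integrating over the
# recruitment density gives the nominal axial stress, and force is stress
# times physiological cross-sectional area.

#' Ligament bundle specification
#'
#' Bundle-level material and geometric parameters of one dense connective
#' tissue (DCT) bundle of the ACL.
#'
#' @param name Bundle label, e.g. `"A-ACL"` (anteromedial) or `"P-ACL"`
#'   (posterolateral).
#' @param resting_length Resting length \eqn{L_r} with the knee in neutral
#'   position, mm.
#' @param cross_sectional_area Physiological cross-sectional area \eqn{A},
#'   mm^2.
#' @param max_isometric_force Maximum isometric force of the bundle
#'   actuator, N.  Forces above this are flagged by [strain_limit_check()]
#'   and [ligament_force()], never clamped.
#' @param elastic_modulus Collagen-fibre elastic modulus \eqn{K}, MPa.
#' @param viscosity Absolute viscosity coefficient \eqn{\eta}, MPa s (it
#'   multiplies a strain rate in 1/s to give a stress in MPa).
#' @param weibull_shape,weibull_scale Shape \eqn{\alpha} and scale
#'   \eqn{\beta} of the Weibull fibre-recruitment distribution
#'   (dimensionless strain units).
#' @param weibull_location Location parameter \eqn{\gamma}; fixed at 0 in
#'   the short-term viscoelastic model.
#' @param passive_strain_cap Passive strain ratio above which fibre damage
#'   and rupture are expected (default 0.15).
#' @param junction_strain_cap Maximum admissible strain at the
#'   ligament--bone junction (default 0.0275, the midpoint of the
#'   2.5--3.0% band).
#'
#' @return An object of class `ligament_bundle`.
#' @seealso [acl_bundles()] for the two default ACL bundles.
#' @export
ligament_bundle <- function(name,
                            resting_length,
                            cross_sectional_area,
                            max_isometric_force,
                            elastic_modulus = 70,
                            viscosity = 20,
                            weibull_shape = 4.5,
                            weibull_scale = 0.3,
                            weibull_location = 0,
                            passive_strain_cap = 0.15,
                            junction_strain_cap = 0.0275) {
  stopifnot(is.character(name), length(name) == 1L)
  if (resting_length <= 0) stop("resting_length must be positive", call. = FALSE)
  if (cross_sectional_area <= 0) stop("cross_sectional_area must be positive", call. = FALSE)
  if (max_isometric_force <= 0) stop("max_isometric_force must be positive", call. = FALSE)
  if (elastic_modulus <= 0) stop("elastic_modulus must be positive", call. = FALSE)
  if (viscosity < 0) stop("viscosity must be non-negative", call. = FALSE)
  if (weibull_shape <= 0 || weibull_scale <= 0) {
    stop("Weibull shape and scale must be positive", call. = FALSE)
  }
  if (weibull_location != 0) {
    stop("weibull_location is fixed at 0 in the short-term model", call. = FALSE)
  }
  if (passive_strain_cap <= 0 || passive_strain_cap >= 1 ||
      junction_strain_cap <= 0 || junction_strain_cap >= 1) {
    stop("strain caps must lie in (0, 1)", call. = FALSE)
  }
  structure(
    list(
      name = name,
      resting_length = resting_length,
      cross_sectional_area = cross_sectional_area,
      max_isometric_force = max_isometric_force,
      elastic_modulus = elastic_modulus,
      viscosity = viscosity,
      weibull_shape = weibull_shape,
      weibull_scale = weibull_scale,
      weibull_location = weibull_location,
      passive_strain_cap = passive_strain_cap,
      junction_strain_cap = junction_strain_cap
    ),
    class = "ligament_bundle"
  )
}

#' @export
print.ligament_bundle <- function(x, ...) {
  cat(sprintf(
    "<ligament_bundle %s>  L_r = %g mm, A = %g mm^2, F_max = %g N\n",
    x$name, x$resting_length, x$cross_sectional_area, x$max_isometric_force
  ))
  cat(sprintf(
    "  K = %g MPa, eta = %g MPa s, Weibull(shape %g, scale %g)\n",
    x$elastic_modulus, x$viscosity, x$weibull_shape, x$weibull_scale
  ))
  invisible(x)
}

#' Default ACL bundle registry
#'
#' The anteromedial (A-ACL) and posterolateral (P-ACL) bundle
#' specifications used throughout the package: resting lengths 30 and
#' 23.36 mm, cross-sectional areas 20.7 and 19.3 mm^2, and maximum
#' isometric forces 1500 and 1600 N, with shared material constants
#' K = 70 MPa, eta = 20 MPa s, and Weibull recruitment parameters
#' shape 4.5, scale 0.3.
#'
#' @return A named list of two [ligament_bundle()] objects.
#' @export
acl_bundles <- function() {
  list(
    `A-ACL` = ligament_bundle("A-ACL", resting_length = 30,
                              cross_sectional_area = 20.7,
                              max_isometric_force = 1500),
    `P-ACL` = ligament_bundle("P-ACL", resting_length = 23.36,
                              cross_sectional_area = 19.3,
                              max_isometric_force = 1600)
  )
}

#' Ligament strain from elongated length
#'
#' Engineering strain \eqn{\epsilon_s = (L_e - L_r) / L_r}.  Negative
#' values indicate a slack ligament and carry zero stress downstream.
#'
#' @param elongated_length Elongated (current) length \eqn{L_e}, mm.
#'   Vectorised.
#' @param resting_length Resting length \eqn{L_r}, mm.
#' @return Dimensionless strain, same length as `elongated_length`.
#' @export
#' @examples
#' compute_strain(33, 30)  # 0.10
compute_strain <- function(elongated_length, resting_length) {
  if (!is.numeric(resting_length) || length(resting_length) != 1L ||
      resting_length <= 0) {
    stop("resting_length must be a positive scalar", call. = FALSE)
  }
  (elongated_length - resting_length) / resting_length
}

#' Instantaneous strain rate
#'
#' Time derivative of the strain series, estimated by central differences
#' with one-sided differences at the endpoints.
#'
#' @param strain_series Dimensionless strain, sampled uniformly.
#' @param dt Sampling interval, s.
#' @return Strain rate in 1/s, same length as the input.
#' @export
compute_strain_rate <- function(strain_series, dt) {
  if (length(strain_series) < 2L) {
    stop("at least two samples are required to estimate a strain rate",
         call. = FALSE)
  }
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  as.numeric(pracma::gradient(strain_series, h1 = dt))
}

#' Weibull fibre-recruitment density
#'
#' Probability density of the strain at which a collagen fibre uncoils
#' and starts carrying load: a two-parameter Weibull distribution
#' (location fixed at zero).  Strains below zero return zero density (no
#' recruitment in a slack ligament).
#'
#' @param strain Dimensionless strain (vectorised).
#' @param shape,scale Weibull shape \eqn{\alpha > 0} and scale
#'   \eqn{\beta > 0}.
#' @return Density values.
#' @export
weibull_recruitment_density <- function(strain, shape = 4.5, scale = 0.3) {
  if (shape <= 0 || scale <= 0) stop("shape and scale must be positive", call. = FALSE)
  out <- numeric(length(strain))
  pos <- strain > 0
  out[pos] <- stats::dweibull(strain[pos], shape = shape, scale = scale)
  out
}

#' Weibull fibre-recruitment cumulative fraction
#'
#' Fraction of fibres recruited at or below a given strain; the CDF
#' matching [weibull_recruitment_density()].
#'
#' @inheritParams weibull_recruitment_density
#' @return Recruited fraction in \[0, 1\].
#' @export
weibull_recruitment_cdf <- function(strain, shape = 4.5, scale = 0.3) {
  if (shape <= 0 || scale <= 0) stop("shape and scale must be positive", call. = FALSE)
  stats::pweibull(pmax(strain, 0), shape = shape, scale = scale)
}

# Closed-form building blocks of the recruitment integral.
#
# G(eps) = int_0^eps W_cdf(s) ds equals the elastic integral
# int_0^eps w(s) (eps - s) ds by integration by parts; it evaluates to
# eps - (beta/alpha) Gamma(1/alpha) P(1/alpha, (eps/beta)^alpha) with P
# the regularised lower incomplete gamma function.
.recruitment_cdf_integral <- function(eps, shape, scale) {
  eps <- pmax(eps, 0)
  eps - (scale / shape) * gamma(1 / shape) *
    stats::pgamma((eps / scale)^shape, shape = 1 / shape)
}

.sigma_elastic_analytic <- function(eps, spec) {
  spec$elastic_modulus *
    .recruitment_cdf_integral(eps, spec$weibull_shape, spec$weibull_scale)
}

.sigma_viscous_analytic <- function(eps, epsdot, spec) {
  spec$viscosity * epsdot *
    weibull_recruitment_cdf(eps, spec$weibull_shape, spec$weibull_scale)
}

.sigma_quadrature <- function(eps, epsdot, spec, abs_tol = 1e-9) {
  integrand <- function(s) {
    stats::dweibull(s, spec$weibull_shape, spec$weibull_scale) *
      (spec$elastic_modulus * (eps - s) + spec$viscosity * epsdot)
  }
  res <- tryCatch(
    stats::integrate(integrand, lower = 0, upper = eps,
                     abs.tol = abs_tol, rel.tol = abs_tol,
                     subdivisions = 500L),
    error = function(e) NULL
  )
  if (!is.null(res) && res$message == "OK") return(res$value)
  # fallback: fixed composite Simpson rule
  n <- 10000L
  s <- seq(0, eps, length.out = n + 1L)
  f <- integrand(s)
  h <- eps / n
  val <- h / 3 * (f[1] + f[n + 1L] +
                    4 * sum(f[seq(2L, n, by = 2L)]) +
                    2 * sum(f[seq(3L, n - 1L, by = 2L)]))
  if (!is.finite(val)) {
    stop("quadrature failed to converge for the stress integral", call. = FALSE)
  }
  val
}

#' Nominal axial stress of a viscoelastic ligament bundle
#'
#' Evaluates the fibre-recruitment stress integral
#' \deqn{\sigma_{af}(\epsilon, \dot\epsilon) = \int_0^{\epsilon}
#'   w(\epsilon_s)\,[K(\epsilon - \epsilon_s) + \eta\,\dot\epsilon]\,
#'   d\epsilon_s,}
#' where \eqn{w} is the Weibull recruitment density of the bundle.  Slack
#' states (\eqn{\epsilon \le 0}) carry zero stress, and the total stress
#' is clamped at zero from below so that a strongly negative strain rate
#' during unloading cannot produce compressive stress.
#'
#' @param strain Dimensionless strain (vectorised).
#' @param strain_rate Strain rate, 1/s; recycled against `strain`.
#' @param spec A [ligament_bundle()].
#' @param method `"quadrature"` (adaptive quadrature with composite
#'   Simpson fallback) or `"analytic"` (closed form via the regularised
#'   incomplete gamma function; equal to machine precision, much faster
#'   on long series).
#' @param abs_tol Absolute tolerance of the adaptive quadrature, MPa.
#' @return Nominal axial stress, MPa.
#' @export
#' @examples
#' aacl <- acl_bundles()[["A-ACL"]]
#' nominal_axial_stress(0.10, 0, aacl)
nominal_axial_stress <- function(strain, strain_rate = 0, spec,
                                 method = c("quadrature", "analytic"),
                                 abs_tol = 1e-9) {
  method <- match.arg(method)
  stopifnot(inherits(spec, "ligament_bundle"))
  n <- max(length(strain), length(strain_rate))
  strain <- rep_len(strain, n)
  strain_rate <- rep_len(strain_rate, n)
  if (method == "analytic") {
    sig <- ifelse(strain <= 0, 0,
                  .sigma_elastic_analytic(strain, spec) +
                    .sigma_viscous_analytic(strain, strain_rate, spec))
    return(pmax(sig, 0))
  }
  out <- numeric(n)
  for (i in seq_len(n)) {
    out[i] <- if (strain[i] <= 0) 0 else {
      max(.sigma_quadrature(strain[i], strain_rate[i], spec, abs_tol), 0)
    }
  }
  out
}

#' Elastic/viscous decomposition of the nominal axial stress
#'
#' Splits the recruitment integral into its elastic part
#' \eqn{\int w\,K(\epsilon - \epsilon_s)\,d\epsilon_s} and viscous part
#' \eqn{\int w\,\eta\dot\epsilon\,d\epsilon_s =
#'   \eta\dot\epsilon\,W_{cdf}(\epsilon)}.  The boundary pressure term is
#' zero (traction-free boundary).
#'
#' @inheritParams nominal_axial_stress
#' @return An object of class `stress_decomposition`: list with elements
#'   `elastic`, `viscous`, `total` (all MPa, total clamped at 0) and
#'   `pressure` (fixed 0).
#' @export
stress_decomposition <- function(strain, strain_rate = 0, spec,
                                 method = c("quadrature", "analytic"),
                                 abs_tol = 1e-9) {
  method <- match.arg(method)
  stopifnot(inherits(spec, "ligament_bundle"))
  n <- max(length(strain), length(strain_rate))
  strain <- rep_len(strain, n)
  strain_rate <- rep_len(strain_rate, n)
  pos <- strain > 0
  elastic <- numeric(n)
  viscous <- numeric(n)
  if (method == "analytic") {
    elastic[pos] <- .sigma_elastic_analytic(strain[pos], spec)
    viscous[pos] <- .sigma_viscous_analytic(strain[pos], strain_rate[pos], spec)
  } else {
    zero_rate_spec <- spec
    for (i in which(pos)) {
      elastic[i] <- .sigma_quadrature(strain[i], 0, zero_rate_spec, abs_tol)
      viscous[i] <- .sigma_quadrature(strain[i], strain_rate[i], spec, abs_tol) -
        elastic[i]
    }
  }
  structure(
    list(elastic = elastic, viscous = viscous,
         total = pmax(elastic + viscous, 0), pressure = 0),
    class = "stress_decomposition"
  )
}

#' Ligament force from nominal axial stress
#'
#' Force is stress times physiological cross-sectional area
#' (MPa x mm^2 = N).  Forces above the bundle's maximum isometric force
#' are flagged through the `"exceeds_max_isometric"` attribute but never
#' clamped: the maximum isometric force is an actuator setting, not a
#' physical ceiling.
#'
#' @param stress Nominal axial stress, MPa (vectorised), must be
#'   non-negative.
#' @param spec A [ligament_bundle()].
#' @return Force in N with attribute `exceeds_max_isometric` (integer
#'   indices of flagged samples).
#' @export
ligament_force <- function(stress, spec) {
  stopifnot(inherits(spec, "ligament_bundle"))
  if (any(stress < 0)) {
    stop("stress must be non-negative (slack states carry zero stress)",
         call. = FALSE)
  }
  force <- stress * spec$cross_sectional_area
  structure(force,
            exceeds_max_isometric = which(force > spec$max_isometric_force))
}

#' Total ACL force
#'
#' The total ACL force is the sample-wise sum of the anteromedial and
#' posterolateral bundle forces.
#'
#' @param force_a_acl,force_p_acl Bundle force series, N, equal length.
#' @return Total force series, N.
#' @export
total_acl_force <- function(force_a_acl, force_p_acl) {
  if (length(force_a_acl) != length(force_p_acl)) {
    stop("bundle force series must have equal length", call. = FALSE)
  }
  as.numeric(force_a_acl) + as.numeric(force_p_acl)
}

#' ACL elongation from knee flexion angle
#'
#' Maps a knee flexion trace to ligament elongated length through a
#' polynomial calibration.  This stands in for the musculoskeletal-model
#' elongation output: no physiological default mapping is asserted, the
#' coefficients come from configuration.  Trials that already carry a
#' measured/simulated elongation column bypass this mapping entirely.
#'
#' @param knee_flexion Knee flexion angle, degrees (vectorised).
#' @param mapping A list with `coefficients` (polynomial coefficients in
#'   increasing order: length = L_e(theta) = c0 + c1 theta + ...) and
#'   `range` (two-element valid flexion range, degrees).
#' @return Elongated length series, mm.
#' @export
acl_elongation_from_knee_flexion <- function(knee_flexion, mapping) {
  if (is.null(mapping$coefficients) || is.null(mapping$range)) {
    stop("mapping must supply 'coefficients' and 'range'", call. = FALSE)
  }
  rng <- sort(mapping$range)
  if (any(knee_flexion < rng[1] | knee_flexion > rng[2])) {
    stop("knee flexion outside the valid range of the elongation mapping",
         call. = FALSE)
  }
  co <- mapping$coefficients
  out <- numeric(length(knee_flexion))
  for (k in seq_along(co)) out <- out + co[k] * knee_flexion^(k - 1)
  out
}

#' Fit the sixth-order material-parameter polynomial
#'
#' Fits a sixth-order polynomial to each (strain, response) sample curve
#' by least squares and averages the coefficients across curves, giving
#' the coefficient matrix used to parameterise the ligament material
#' response in simulation.
#'
#' @param curves A list of curves; each curve is a two-column matrix or
#'   data frame (strain, response) with at least 7 points.
#' @return An object of class `material_fit`: list with `coefficients`
#'   (length-7 mean coefficient vector, increasing powers), `per_curve`
#'   (matrix, one row per curve), `sample_count` (number of curves) and
#'   `fit_residual` (RMS residual across all curves).
#' @export
fit_material_polynomial <- function(curves) {
  if (!is.list(curves) || length(curves) < 1L) {
    stop("at least one sample curve is required", call. = FALSE)
  }
  per <- matrix(NA_real_, nrow = length(curves), ncol = 7L)
  resid2 <- 0
  npts <- 0L
  for (i in seq_along(curves)) {
    cv <- as.matrix(curves[[i]])
    if (ncol(cv) != 2L || nrow(cv) < 7L) {
      stop("each curve needs two columns and at least 7 points", call. = FALSE)
    }
    x <- cv[, 1]; y <- cv[, 2]
    X <- outer(x, 0:6, `^`)
    qrX <- qr(X)
    if (qrX$rank < 7L) {
      stop("rank-deficient design: strain values do not support a sixth-order fit",
           call. = FALSE)
    }
    beta <- qr.coef(qrX, y)
    per[i, ] <- beta
    resid2 <- resid2 + sum((y - X %*% beta)^2)
    npts <- npts + length(y)
  }
  structure(
    list(coefficients = colMeans(per), per_curve = per,
         sample_count = length(curves),
         fit_residual = sqrt(resid2 / npts)),
    class = "material_fit"
  )
}

#' Strain-limit validation report
#'
#' Checks a strain series against the bundle's passive strain cap
#' (fibre-damage threshold, default 15%) and, optionally, the
#' ligament-bone junction cap (default 2.5--3.0% band midpoint) on a
#' configured sub-interval of samples.  The data are never modified:
#' violations are reported, not clamped.
#'
#' @param strain_series Dimensionless strain series.
#' @param spec A [ligament_bundle()].
#' @param junction_window Optional integer index range (two elements)
#'   delimiting the junction-region samples to check against the
#'   junction cap.
#' @return An object of class `strain_limit_report`: list with
#'   `passive_violations` (indices above the passive cap), `passive_cap`,
#'   `junction_exceeded` (logical or NA when no window given),
#'   `junction_cap`, and `n_samples`.
#' @export
strain_limit_check <- function(strain_series, spec, junction_window = NULL) {
  stopifnot(inherits(spec, "ligament_bundle"))
  viol <- which(strain_series > spec$passive_strain_cap)
  junction <- NA
  if (!is.null(junction_window)) {
    idx <- seq.int(junction_window[1], junction_window[2])
    junction <- any(strain_series[idx] > spec$junction_strain_cap)
  }
  structure(
    list(passive_violations = viol,
         passive_cap = spec$passive_strain_cap,
         junction_exceeded = junction,
         junction_cap = spec$junction_strain_cap,
         n_samples = length(strain_series)),
    class = "strain_limit_report"
  )
}

#' @export
print.strain_limit_report <- function(x, ...) {
  cat(sprintf("<strain_limit_report> %d/%d samples above passive cap %.3g\n",
              length(x$passive_violations), x$n_samples, x$passive_cap))
  if (!is.na(x$junction_exceeded)) {
    cat(sprintf("  junction cap %.3g exceeded: %s\n", x$junction_cap,
                x$junction_exceeded))
  }
  invisible(x)
}

#' Total ACL force trace from an elongation series
#'
#' Runs the full constitutive chain on an A-ACL elongation trace: strain
#' (relative to the A-ACL resting length), strain rate by central
#' differences, nominal axial stress, and total force.  Both bundles are
#' assumed to share the same strain history (equal-strain assumption for
#' a common elongation input), so the total force is the shared stress
#' times the summed cross-sectional area.
#'
#' @param elongation Elongated length trace of the A-ACL, mm.
#' @param dt Sampling interval, s.
#' @param bundles Bundle registry as returned by [acl_bundles()].
#' @param method Stress evaluation method, see [nominal_axial_stress()].
#' @return Total ACL force series, N.
#' @export
acl_force_trace <- function(elongation, dt, bundles = acl_bundles(),
                            method = "analytic") {
  ref <- bundles[[1L]]
  eps <- compute_strain(elongation, ref$resting_length)
  epsdot <- compute_strain_rate(eps, dt)
  sigma <- nominal_axial_stress(eps, epsdot, ref, method = method)
  area <- sum(vapply(bundles, function(b) b$cross_sectional_area, numeric(1)))
  sigma * area
}
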