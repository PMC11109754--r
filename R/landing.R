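# Landing-phase biomechanics: phase detection, filtering, joint power,
# energy dissipation and scalar summary extraction.
#
# Sign conventions (declared once, used everywhere):
#   * ankle sagittal angle: plantarflexion positive, dorsiflexion negative;
#   * ankle frontal angle: inversion positive;
#   * sagittal moments are stored physiologically signed so that joint
#     power (moment x angular velocity) is negative during the absorption
#     phase; peak moments are reported as positive magnitudes.

#' Per-trial synchronised time-series container
#'
#' All channels must share one common, uniformly sampled time grid
#' (resample before construction if kinematics and kinetics were
#' recorded at different rates).
#'
#' @param time Time stamps, s (monotone increasing, uniform).
#' @param vgrf Vertical ground reaction force, N (absolute, not
#'   mass-normalised; thresholding for contact detection needs newtons).
#' @param ankle_angle Ankle sagittal angle, deg (plantarflexion
#'   positive).
#' @param knee_angle Knee flexion angle, deg (flexion positive).
#' @param hip_angle Hip flexion angle, deg.
#' @param ankle_inversion Ankle frontal (inversion) angle, deg
#'   (inversion positive).
#' @param ankle_moment,knee_moment,hip_moment Sagittal joint moments,
#'   Nm/kg.
#' @param inversion_moment Ankle frontal-plane moment.  Carried in the
#'   unit declared by `inversion_moment_unit`; the tabulated unit in the
#'   source protocol is "N/kg", which is carried as metadata rather than
#'   silently corrected to Nm/kg.
#' @param body_mass Subject body mass, kg.
#' @param acl_elongation Optional A-ACL elongated length trace, mm.
#' @param inversion_moment_unit Unit string for `inversion_moment`
#'   (default `"N/kg"`).
#' @return An object of class `trial_time_series` (a data frame with
#'   attributes `body_mass`, `fs`, `inversion_moment_unit`).
#' @export
trial_time_series <- function(time, vgrf, ankle_angle, knee_angle, hip_angle,
                              ankle_inversion, ankle_moment, knee_moment,
                              hip_moment, inversion_moment, body_mass,
                              acl_elongation = NULL,
                              inversion_moment_unit = "N/kg") {
  n <- length(time)
  chans <- list(vgrf = vgrf, ankle_angle = ankle_angle,
                knee_angle = knee_angle, hip_angle = hip_angle,
                ankle_inversion = ankle_inversion,
                ankle_moment = ankle_moment, knee_moment = knee_moment,
                hip_moment = hip_moment, inversion_moment = inversion_moment)
  if (!is.null(acl_elongation)) chans$acl_elongation <- acl_elongation
  if (any(vapply(chans, length, integer(1)) != n)) {
    stop("all channels must match the length of the time vector", call. = FALSE)
  }
  dtv <- diff(time)
  if (any(dtv <= 0)) stop("time must be strictly increasing", call. = FALSE)
  if (diff(range(dtv)) > 1e-6 * mean(dtv)) {
    stop("time grid must be uniform; resample channels first", call. = FALSE)
  }
  if (body_mass <= 0) stop("body_mass must be positive", call. = FALSE)
  df <- data.frame(time = time, chans)
  structure(df,
            body_mass = body_mass,
            fs = 1 / mean(dtv),
            inversion_moment_unit = inversion_moment_unit,
            class = c("trial_time_series", "data.frame"))
}

#' Detect the landing phase
#'
#' The landing phase runs from the initial contact sample (first vertical
#' GRF sample above the contact threshold, default 10 N) to the maximum
#' knee flexion at or after contact.  Thresholding is done on the raw
#' (unfiltered) absolute force to avoid filter ringing around impact.
#'
#' @param vgrf Vertical ground reaction force, N.
#' @param knee_flexion Knee flexion angle, deg.
#' @param threshold Contact threshold, N (default 10).
#' @return Integer vector `c(start, end)` of sample indices.
#' @export
detect_landing_phase <- function(vgrf, knee_flexion, threshold = 10) {
  if (length(vgrf) != length(knee_flexion)) {
    stop("vgrf and knee_flexion must have equal length", call. = FALSE)
  }
  above <- which(vgrf > threshold)
  if (length(above) == 0L) {
    stop(sprintf("contact threshold %g N never crossed", threshold),
         call. = FALSE)
  }
  start <- above[1L]
  end <- start - 1L + which.max(knee_flexion[start:length(knee_flexion)])
  if (end <= start) {
    stop("maximum knee flexion coincides with initial contact; no landing phase",
         call. = FALSE)
  }
  c(start = start, end = end)
}

#' Zero-phase low-pass filtering of a biomechanical signal
#'
#' Fourth-order zero-phase Butterworth low-pass filtering, implemented as
#' a forward-backward pass of a second-order design with odd-reflection
#' edge padding.  The conventional cutoffs are 10 Hz for kinematic and
#' 20 Hz for kinetic channels.
#'
#' @param x Signal series.
#' @param fs Sampling rate, Hz.
#' @param kind `"kinematic"` (10 Hz) or `"kinetic"` (20 Hz); ignored
#'   when `cutoff` is given explicitly.
#' @param cutoff Optional explicit cutoff, Hz.
#' @return Filtered series, same length.
#' @export
filter_signal <- function(x, fs, kind = c("kinematic", "kinetic"),
                          cutoff = NULL) {
  if (is.null(cutoff)) {
    kind <- match.arg(kind)
    cutoff <- if (kind == "kinematic") 10 else 20
  }
  .butter_lowpass(x, fs, cutoff)
}

#' Normalise a series to the 101-point landing phase
#'
#' Linearly interpolates a window of samples onto 0--100% of the landing
#' phase in 1% steps (101 points), preserving the endpoints exactly.
#'
#' @param x Signal series.
#' @param window Optional two-element index range delimiting the phase;
#'   defaults to the whole series.
#' @param n_points Number of output points (default 101).
#' @return Interpolated series of length `n_points`.
#' @export
time_normalize <- function(x, window = NULL, n_points = 101L) {
  if (!is.null(window)) x <- x[seq.int(window[1], window[2])]
  m <- length(x)
  if (m < 2L) stop("window must contain at least two samples", call. = FALSE)
  stats::approx(seq_len(m), x, xout = seq(1, m, length.out = n_points))$y
}

#' Joint power
#'
#' Joint power is the product of the joint moment and the joint angular
#' velocity; negative power marks eccentric (energy-absorbing) work.
#'
#' @param moment Joint moment series, Nm/kg.
#' @param angular_velocity Joint angular velocity series, rad/s.
#' @return Power series, W/kg.
#' @export
joint_power <- function(moment, angular_velocity) {
  if (length(moment) != length(angular_velocity)) {
    stop("moment and angular velocity must have equal length", call. = FALSE)
  }
  moment * angular_velocity
}

#' Joint energy dissipation
#'
#' Trapezoidal integral of the negative (eccentric) part of the joint
#' power over time, reported as a positive dissipation magnitude.
#'
#' @param power Joint power series, W/kg.
#' @param time Time stamps, s (monotone increasing).
#' @return Energy dissipation, J/kg (non-negative scalar).
#' @export
energy_dissipation <- function(power, time) {
  if (any(diff(time) <= 0)) stop("time must be strictly increasing", call. = FALSE)
  -pracma::trapz(time, pmin(power, 0))
}

#' Total energy dissipation (TED)
#'
#' Sum of the sagittal-plane ankle, knee and hip energy dissipations.
#' Frontal and transverse contributions are excluded by contract: lower
#' limb energy dissipation during single-leg landing is concentrated in
#' the sagittal plane.
#'
#' @param ankle,knee,hip Per-joint dissipations, J/kg.
#' @return TED, J/kg.
#' @export
total_energy_dissipation <- function(ankle, knee, hip) {
  vals <- c(ankle = ankle, knee = knee, hip = hip)
  if (any(is.na(vals))) stop("all three joint dissipations are required", call. = FALSE)
  sum(vals)
}

#' Extract the per-trial scalar summary variables
#'
#' Runs the standard landing pipeline on one trial: landing-phase
#' detection on the raw force, zero-phase filtering (10 Hz kinematic /
#' 20 Hz kinetic), then extraction of
#' \itemize{
#'   \item AICA: ankle plantarflexion angle at the initial contact sample
#'     (deg);
#'   \item AROM: sagittal excursion from AICA to the peak dorsiflexion
#'     (deg);
#'   \item PVGRF: peak vertical GRF, N/kg;
#'   \item TED: total sagittal energy dissipation, J/kg, from joint power
#'     (moment times angular velocity, angles differentiated centrally
#'     and converted to rad/s);
#'   \item PADM/PKFM/PHFM: peak sagittal moment magnitudes, Nm/kg;
#'   \item PAIA: peak ankle inversion angle (deg) and PAIM: peak frontal
#'     moment magnitude (unit carried from the trial metadata);
#'   \item PAF: peak total ACL force from the viscoelastic ligament model
#'     applied to the elongation trace, N/kg (NA when the trial carries
#'     no elongation channel).  The elongation channel is treated as a
#'     model output and is not low-pass filtered.
#' }
#' All peaks are taken strictly within the detected phase.
#'
#' @param trial A [trial_time_series()].
#' @param bundles Ligament bundle registry for the ACL force chain.
#' @param apply_filters Set to `FALSE` when the channels are already
#'   filtered/band-limited.
#' @param stress_method Stress evaluation method for the ACL chain
#'   (default `"analytic"`; `"quadrature"` gives the reference adaptive
#'   integration at higher cost).
#' @return An object of class `trial_summary` (a one-row data frame).
#' @export
extract_summary <- function(trial, bundles = acl_bundles(),
                            apply_filters = TRUE,
                            stress_method = "analytic") {
  stopifnot(inherits(trial, "trial_time_series"))
  fs <- attr(trial, "fs")
  mass <- attr(trial, "body_mass")
  dt <- 1 / fs
  phase <- detect_landing_phase(trial$vgrf, trial$knee_angle)
  idx <- seq.int(phase["start"], phase["end"])

  kin <- function(x) if (apply_filters) filter_signal(x, fs, "kinematic") else x
  kinet <- function(x) if (apply_filters) filter_signal(x, fs, "kinetic") else x

  ankle <- kin(trial$ankle_angle)
  knee <- kin(trial$knee_angle)
  hip <- kin(trial$hip_angle)
  inversion <- kin(trial$ankle_inversion)
  vgrf <- kinet(trial$vgrf)
  m_ankle <- kinet(trial$ankle_moment)
  m_knee <- kinet(trial$knee_moment)
  m_hip <- kinet(trial$hip_moment)
  m_inv <- kinet(trial$inversion_moment)

  aica <- ankle[phase["start"]]
  arom <- aica - min(ankle[idx])
  pvgrf <- max(vgrf[idx]) / mass

  deg2rad <- pi / 180
  omega <- function(angle) compute_strain_rate(angle, dt) * deg2rad
  diss <- function(moment, angle) {
    p <- joint_power(moment, omega(angle))
    energy_dissipation(p[idx], trial$time[idx])
  }
  ted <- total_energy_dissipation(diss(m_ankle, ankle),
                                  diss(m_knee, knee),
                                  diss(m_hip, hip))

  paf <- NA_real_
  if (!is.null(trial$acl_elongation)) {
    force <- acl_force_trace(trial$acl_elongation, dt, bundles,
                             method = stress_method)
    paf <- max(force[idx]) / mass
  }

  out <- data.frame(
    AICA = aica,
    AROM = arom,
    PVGRF = pvgrf,
    TED = ted,
    PADM = max(abs(m_ankle[idx])),
    PKFM = max(abs(m_knee[idx])),
    PHFM = max(abs(m_hip[idx])),
    PAIA = max(inversion[idx]),
    PAIM = max(abs(m_inv[idx])),
    PAF = paf
  )
  structure(out,
            phase = phase,
            inversion_moment_unit = attr(trial, "inversion_moment_unit"),
            class = c("trial_summary", "data.frame"))
}
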