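# Trial-level waveform synthesis.
#
# Waveforms are built from smooth bump/ramp primitives (raised-cosine
# impact transient, smoothstep angle transitions) chosen so that the
# embedded summary values are recoverable in closed form by the landing
# metrics pipeline: the plantarflexed initial contact transitions to
# peak dorsiflexion, the vertical GRF has a single impact peak before
# settling on body weight, joint power is negative during absorption,
# and the ACL elongation trace is inverted through the viscoelastic
# ligament model so that the extracted peak ACL force matches the
# summary row.

.smoothstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u * u * (3 - 2 * u)
}

.hann_bump <- function(u) {
  ifelse(u > 0 & u < 1, 0.5 * (1 - cos(2 * pi * u)), 0)
}

#' Waveform template parameters
#'
#' Temporal layout and shape parameters of a synthetic single-leg
#' landing trial.  Defaults: 200 Hz common grid, 0.2 s of pre-contact
#' flight, a 0.4 s landing (absorption) phase ending at maximum knee
#' flexion, a 0.1 s impact transient peaking 50 ms after contact, and a
#' knee flexion excursion from 5 to 70 degrees.
#'
#' @param fs Sampling rate of the common grid, Hz.
#' @param pre_contact Flight time before initial contact, s.
#' @param landing_duration Duration of the landing phase (contact to
#'   maximum knee flexion), s.
#' @param post_phase Recorded time after maximum knee flexion, s.
#' @param impact_width Width of the raised-cosine impact transient, s.
#'   The default 0.16 s (force peak 80 ms after contact) keeps the
#'   transient inside the passband of the 20 Hz kinetic filter so that
#'   the embedded peak survives filtering.
#' @param knee_start,knee_max Knee flexion at contact and at the end of
#'   the phase, deg.
#' @param hip_start,hip_max Hip flexion at contact and phase end, deg.
#' @return A list of class `waveform_template`.
#' @export
waveform_template <- function(fs = 200, pre_contact = 0.2,
                              landing_duration = 0.4, post_phase = 0.1,
                              impact_width = 0.16, knee_start = 5,
                              knee_max = 70, hip_start = 10, hip_max = 50) {
  if (landing_duration <= impact_width / 2) {
    stop("landing_duration must exceed half the impact width", call. = FALSE)
  }
  structure(
    list(fs = fs, pre_contact = pre_contact,
         landing_duration = landing_duration, post_phase = post_phase,
         impact_width = impact_width, knee_start = knee_start,
         knee_max = knee_max, hip_start = hip_start, hip_max = hip_max),
    class = "waveform_template"
  )
}

# Peak total ACL force (over the landing phase) produced by an
# elongation template with peak strain eps_max, evaluated through the
# same discrete strain-rate and stress chain the extraction pipeline
# uses.
.peak_force_for_eps <- function(eps_max, shape01, dt, phase_idx, bundles) {
  ref <- bundles[[1L]]
  elong <- ref$resting_length * (1 + eps_max * shape01)
  force <- acl_force_trace(elong, dt, bundles, method = "analytic")
  max(force[phase_idx])
}

#' Generate trial waveforms embedding a summary row
#'
#' Builds a full synthetic trial (GRF, sagittal angles, inversion angle,
#' joint moments, ACL elongation) whose extracted summary recovers the
#' embedded AICA, AROM, PVGRF, peak moments and PAIA of the supplied
#' row, and whose elongation trace is numerically inverted through the
#' viscoelastic ligament model so that the extracted PAF matches the
#' row.  The trial-level TED implied by the moment and angle templates
#' is whatever the templates yield; TED calibration lives at the summary
#' level.
#'
#' @param row A one-row data frame (or named list/vector) with the
#'   summary variables `AICA`, `AROM`, `PVGRF`, `PADM`, `PKFM`, `PHFM`,
#'   `PAIA`, `PAIM`, `PAF` (PAF may be `NA` to skip the elongation
#'   channel).
#' @param body_mass Subject body mass, kg (default 81.93, the cohort
#'   mean).
#' @param template A [waveform_template()].
#' @param bundles Ligament bundle registry used for the elongation
#'   inversion.
#' @param noise_sd Optional additive white measurement noise SD applied
#'   to every channel (default 0: noiseless templates).
#' @param seed Optional seed for the measurement noise.
#' @return A [trial_time_series()] with attribute `embedded` (the input
#'   row as a named numeric vector).
#' @export
generate_trial_waveforms <- function(row, body_mass = 81.93,
                                     template = waveform_template(),
                                     bundles = acl_bundles(),
                                     noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  row <- unlist(row)
  need <- c("AICA", "AROM", "PVGRF", "PADM", "PKFM", "PHFM", "PAIA", "PAIM")
  if (any(!need %in% names(row))) {
    stop("summary row is missing required variables", call. = FALSE)
  }
  if (row[["AROM"]] < 0) stop("infeasible summary: AROM < 0", call. = FALSE)
  if (row[["PVGRF"]] <= 0) stop("infeasible summary: PVGRF <= 0", call. = FALSE)

  tp <- template
  dt <- 1 / tp$fs
  t_end <- tp$pre_contact + tp$landing_duration + tp$post_phase
  time <- seq(0, t_end, by = dt)
  n <- length(time)
  t0 <- tp$pre_contact
  u <- (time - t0) / tp$landing_duration       # 0..1 over the phase
  in_phase <- time >= t0 & time <= t0 + tp$landing_duration

  # vertical GRF: raised-cosine impact transient on top of a smooth
  # rise to body weight; zero in flight
  bw <- body_mass * 9.81
  f_peak <- row[["PVGRF"]] * body_mass
  ui <- (time - t0) / tp$impact_width
  base <- bw * .smoothstep(ui)
  amp <- f_peak - bw * .smoothstep(0.5)
  if (amp <= 0) stop("infeasible summary: PVGRF below the body-weight plateau",
                     call. = FALSE)
  vgrf <- ifelse(time < t0, 0, base + amp * .hann_bump(ui))

  # sagittal angles: smoothstep transitions over the phase
  ankle <- row[["AICA"]] - row[["AROM"]] * .smoothstep(u)
  knee <- tp$knee_start + (tp$knee_max - tp$knee_start) * .smoothstep(u)
  # strictly decreasing after the phase so the knee maximum is unique
  post <- time > t0 + tp$landing_duration
  knee[post] <- tp$knee_max - 5 * (time[post] - (t0 + tp$landing_duration))
  hip <- tp$hip_start + (tp$hip_max - tp$hip_start) * .smoothstep(u)

  # frontal plane: inversion bump peaking mid-phase
  inversion <- row[["PAIA"]] * .hann_bump(u)

  # moments: signed so that power (moment x angular velocity) is
  # negative during absorption; peaks are reported as magnitudes
  m_ankle <- row[["PADM"]] * .hann_bump(u)     # ankle velocity < 0
  m_knee <- -row[["PKFM"]] * .hann_bump(u)     # knee velocity > 0
  m_hip <- -row[["PHFM"]] * .hann_bump(u)
  m_inv <- row[["PAIM"]] * .hann_bump(u)

  # ACL elongation: smoothstep to a peak strain inverted through the
  # ligament model so the extracted peak force matches PAF
  elong <- NULL
  if ("PAF" %in% names(row) && is.finite(row[["PAF"]])) {
    phase_idx <- which(in_phase)
    shape01 <- .smoothstep(u)
    shape01[post] <- 1
    target <- row[["PAF"]] * body_mass
    f <- function(em) {
      .peak_force_for_eps(em, shape01, dt, phase_idx, bundles) - target
    }
    upper <- 1.5
    while (f(upper) < 0 && upper < 24) upper <- upper * 2
    if (f(upper) < 0) {
      stop("infeasible summary: target peak ACL force out of model range",
           call. = FALSE)
    }
    eps_max <- stats::uniroot(f, c(1e-8, upper), tol = 1e-12)$root
    ref <- bundles[[1L]]
    elong <- ref$resting_length * (1 + eps_max * shape01)
  }

  if (noise_sd > 0) {
    jitter <- function(x) x + stats::rnorm(n, sd = noise_sd)
    vgrf <- pmax(jitter(vgrf), 0)
    ankle <- jitter(ankle); knee <- jitter(knee); hip <- jitter(hip)
    inversion <- jitter(inversion)
    m_ankle <- jitter(m_ankle); m_knee <- jitter(m_knee)
    m_hip <- jitter(m_hip); m_inv <- jitter(m_inv)
  }

  out <- trial_time_series(
    time = time, vgrf = vgrf, ankle_angle = ankle, knee_angle = knee,
    hip_angle = hip, ankle_inversion = inversion, ankle_moment = m_ankle,
    knee_moment = m_knee, hip_moment = m_hip, inversion_moment = m_inv,
    body_mass = body_mass, acl_elongation = elong
  )
  attr(out, "embedded") <- row
  out
}

#' Generate a synthetic raw EMG trace
#'
#' Amplitude-modulated band-limited noise: zero-mean white noise is
#' band-passed to the EMG band (default 10--400 Hz), normalised to unit
#' RMS, and multiplied by a burst envelope built from raised-cosine
#' bursts.  The preprocessing chain applied to such a trace recovers an
#' envelope proportional to the generating one.
#'
#' @param duration Trace duration, s.
#' @param fs Sampling rate, Hz (default 1000).
#' @param bursts A list of bursts, each a list/vector with `center` (s),
#'   `width` (s) and `amplitude` (mV).
#' @param band Carrier noise band, Hz.
#' @param muscle Muscle label.
#' @param is_mvc Mark the trace as an MVC reference.
#' @param seed Optional seed.
#' @return An [emg_trace()] with attribute `envelope` (the generating
#'   envelope).
#' @export
generate_emg <- function(duration = 1, fs = 1000,
                         bursts = list(list(center = 0.5, width = 0.3,
                                            amplitude = 1)),
                         band = c(10, 400), muscle = "muscle",
                         is_mvc = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration * fs)
  time <- (seq_len(n) - 1) / fs
  env <- numeric(n)
  for (b in bursts) {
    b <- unlist(b)
    env <- env + b[["amplitude"]] *
      .hann_bump((time - (b[["center"]] - b[["width"]] / 2)) / b[["width"]])
  }
  carrier <- .butter_bandpass(stats::rnorm(n), fs, band)
  carrier <- carrier / sqrt(mean(carrier^2))
  tr <- emg_trace(env * carrier, sampling_rate = fs, muscle = muscle,
                  is_mvc = is_mvc)
  attr(tr, "envelope") <- env
  tr
}
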