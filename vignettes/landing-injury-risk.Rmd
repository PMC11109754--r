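---
title: "Modelling ACL loading and injury-risk trade-offs in single-leg landings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling ACL loading and injury-risk trade-offs in single-leg landings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(landrisk)
```

## The problem

Single-leg drop landings concentrate large impact loads on one limb within a
few hundred milliseconds. Two injuries dominate this task: non-contact
anterior cruciate ligament (ACL) rupture at the knee, and lateral ankle
sprain (LAS). The ankle motion pattern at touchdown — the plantarflexion
angle at initial contact (AICA) and the sagittal range of motion during
absorption (AROM) — is under voluntary control and modulates both risks, but
in opposite directions: a flatter, stiffer landing raises impact force and
ACL load, while a more plantarflexed, larger-excursion landing raises the
peak inversion angle that drives ankle sprain. `landrisk` implements the
full analysis chain needed to study this trade-off: a viscoelastic ACL force
model, an EMG-driven activation model used to validate musculoskeletal
simulations, landing summary metrics, correlation/risk statistics, and a
calibrated synthetic cohort generator that makes the whole pipeline testable
without access to motion-capture data.

## The viscoelastic ligament model

The ACL is treated as dense connective tissue: a bundle of collagen fibres
that uncoil and begin to carry load sequentially as the ligament stretches.
Strain is engineering strain against the neutral-knee resting length,
$\epsilon_s = (L_e - L_r)/L_r$, and the instantaneous strain rate
$\dot\epsilon$ is its time derivative (central differences on the sample
grid; the differentiation scheme is a package choice, as source protocols
for this model class compute elongation in external simulation software).
The strain at which a fibre is recruited follows a two-parameter Weibull
distribution $w(\epsilon_s)$ with shape $\alpha = 4.5$ and scale
$\beta = 0.3$ (location fixed at zero). Each recruited fibre contributes a
linear elastic stress with modulus $K = 70$ MPa plus a viscous stress
$\eta\,\dot\epsilon$ with $\eta = 20$ MPa s, giving the nominal axial
stress

$$\sigma_{af}(\epsilon, \dot\epsilon) \;=\; \int_0^{\epsilon}
  w(\epsilon_s)\,\bigl[K(\epsilon - \epsilon_s) +
  \eta\,\dot\epsilon\bigr]\, d\epsilon_s ,$$

with zero boundary pressure, zero stress for slack states
($\epsilon \le 0$), and force $F_{af} = \sigma_{af} A$ over the
physiological cross-sectional area. Total ACL force sums the anteromedial
bundle (A-ACL: $L_r = 30$ mm, $A = 20.7$ mm$^2$, max isometric force
1500 N) and the posterolateral bundle (P-ACL: $L_r = 23.36$ mm,
$A = 19.3$ mm$^2$, 1600 N); when one elongation trace feeds both bundles
the package assumes equal strain histories, so total force is the shared
stress times the summed area.

Numerical choices:

* The viscosity unit is taken as MPa s (a viscosity must multiply a 1/s
  rate to yield MPa); the value 20 is configurable.
* The integral is evaluated two ways: adaptive quadrature
  (`stats::integrate`, absolute tolerance $10^{-9}$ MPa, with a
  10\,000-node composite Simpson fallback), and a closed form — by parts,
  the elastic term is $K\int_0^\epsilon W_{cdf}$, expressible through the
  regularised incomplete gamma function, and the viscous term is
  $\eta\,\dot\epsilon\,W_{cdf}(\epsilon)$. The two routes agree to
  $10^{-8}$ relative and both are checked against a $10^6$-node
  trapezoidal oracle in the test suite; the fast closed form is used on
  long traces.
* A negative strain rate during unloading is kept in the integrand (it
  reduces stress) but total stress is clamped at zero: the model defines
  stress only for tension.
* Forces above the maximum isometric force are *flagged*, never clamped —
  that parameter is an actuator setting, not a physical ceiling. Strain
  caps (15% passive fibre-damage threshold; 2.5–3.0% at the
  ligament–bone junction) are validation checks (`strain_limit_check()`),
  not mutations.

A consequence worth stating plainly: with recruitment centred near 30%
strain ($\beta = 0.3$), the model produces only fractions of a megapascal
below the 15% strain cap. Reproducing peak ACL forces of the published
magnitude (≈14.7 N/kg, i.e. ≈1.2 kN at the cohort mean body mass)
therefore requires peak strains well above the physiological caps. The
package treats the printed material constants as given, inverts the model
faithfully, and lets `strain_limit_check()` report the violations rather
than silently rescaling any parameter.

## EMG-driven activation

Raw surface EMG (1000 Hz) is band-passed 10–400 Hz, full-wave rectified,
and low-passed at 6 Hz into a linear envelope; "fourth-order zero-phase"
filtering is implemented as a forward–backward pass of a second-order
Butterworth design (the common reading of that phrase; a forward–backward
fourth-order design is one argument away). The envelope is normalised by
the peak of the maximal-voluntary-contraction (MVC) envelope — the
protocol wording is ambiguous between envelope peak and windowed RMS peak,
so the RMS variant is available by flag. Values above 1 are preserved and
flagged, and whether excitation is clipped to $[0,1]$ before the recursion
is surfaced as a warning rather than silent behaviour.

Neural activation follows the stable second-order recursion
$u(t) = \alpha\,e(t-d) - \beta_1 u(t-1) - \beta_2 u(t-2)$ with
electromechanical delay $d = 10$ ms (rounded to whole samples),
$\beta_1 = C_1 + C_2$, $\beta_2 = C_1 C_2$, $|C_i| < 1$, and the gain
pinned to $\alpha = 1 + \beta_1 + \beta_2$ so constant full excitation
converges to $u = 1$. The roots are never published for this protocol;
the package defaults to $C_1 = C_2 = -0.5$ (mid-range of the stable
region) and exposes them. Muscle activation applies
$a = (e^{A u} - 1)/(e^A - 1)$ with shape $A = 1.5$ and the analytic limit
$a = u$ at $A = 0$. `compare_activation()` provides the RMS/Pearson/peak
agreement metrics used to compare EMG-derived and simulated activations
on the 101-point landing phase.

## Landing metrics

The landing phase runs from the first vertical ground-reaction-force
sample above 10 N (thresholded on the raw force in newtons, to avoid
filter ringing at impact) to maximum knee flexion. Kinematics are filtered
at 10 Hz and kinetics at 20 Hz (fourth-order zero-phase Butterworth).
Sign conventions: plantarflexion and inversion positive; sagittal moments
are stored physiologically signed so joint power (moment × angular
velocity, angles differentiated centrally and converted to rad/s) is
negative during absorption, while peak moments are reported as
magnitudes. Per-joint energy dissipation integrates the negative part of
joint power (trapezoidal rule) and is reported positive; total energy
dissipation (TED) sums ankle, knee and hip sagittal dissipation only.
AROM is the sagittal excursion from AICA to peak dorsiflexion —
sagittal-only, consistent with the TED convention. The tabulated
frontal-plane "ankle inversion moment (N/kg)" unit is carried as metadata
(`inversion_moment_unit`) rather than silently corrected to Nm/kg.
`time_normalize()` maps any phase window onto the standard 101-point
(0–100%) curve with exact endpoints.

## Risk statistics

Correlation analysis uses Pearson $r$ with the two-sided p-value from the
$t$ transform on $n-2$ degrees of freedom and the least-squares line
($R^2 = r^2$ identically, p-values unadjusted). The unit of analysis is
the within-subject trial mean ($n = 60$); pooled-trial analysis is a
configuration away. Peak ACL force (PAF) and peak ankle inversion angle
(PAIA) are min–max standardised over the cohort — maximum observed value
mapped to risk 1, minimum to 0 — and each standardised risk is fitted
linearly on the predictor (AICA or AROM). The crossing of the two fitted
lines is the trade-off point, and the *balanced range* is the interval on
which the fitted risks differ by at most a tolerance $\tau$:
crossing $\pm\ \tau/|b_1 - b_2|$. The default $\tau = 0.25$ (a quarter of
the standardised risk scale) was chosen once so that cohorts with the
calibrated summary statistics yield bands of roughly 10° of AICA and 20°
of AROM, the width scale of the published recommendations; line fits
(rather than smoothed curves) are used because the analysis is framed
throughout in linear-regression terms.

## The synthetic cohort generator

No subject data are deposited for this protocol, so the generator *is*
the study condition. Subject-level summary vectors for the ten variables
(AICA, AROM, PVGRF, TED, PADM, PKFM, PHFM, PAIA, PAIM, PAF) are drawn
from a multivariate normal distribution — the published cohort passed
Kolmogorov–Smirnov normality checks — with the published means and SDs
(e.g. AICA 33.47 ± 5.16°, AROM 59.99 ± 8.35°, PVGRF 36.61 ± 5.10 N/kg,
PAF 14.72 ± 1.68 N/kg) and the published correlations of every variable
with the two anchors AICA and AROM.

Correlations between non-anchor pairs are not published. They are filled
by a two-factor model: each non-anchor variable is represented by its
loadings on the two anchors (solving a 2×2 system per variable), and
implied pair correlations follow from the factor covariance. This
construction reproduces every anchored correlation exactly and is
positive semidefinite whenever the implied communalities stay below 1
(they do; a nearest-correlation-matrix projection via `Matrix::nearPD`
backs up user-supplied calibrations, with the Frobenius distance moved
recorded). The one remaining free quantity, the AICA–AROM correlation
itself, is solved in closed form so that the implied cross-risk
correlation r(PAF, PAIA) equals the published −0.330; the solution is
0.402, a moderate positive association consistent with larger contact
angles accompanying larger excursions. Within-subject trial noise is
added at an SD of 0.2 of the between-subject SD — the protocol never
reports within-subject variance, so this is a documented free parameter;
at 5 trials it attenuates subject-mean correlations by under 1%.

Trial-level waveforms are built from smooth primitives chosen for
closed-form extractable peaks: a raised-cosine impact transient on top of
a smooth rise to body weight (single VGRF peak), smoothstep sagittal
angle transitions from the plantarflexed contact angle to peak
dorsiflexion (and rising knee/hip flexion ending at maximum knee
flexion), and raised-cosine bumps for inversion angle and joint moments.
Defaults: 200 Hz common grid, 0.2 s flight, 0.4 s absorption phase, force
peak 80 ms after contact. The 0.16 s impact-transient width keeps the
template inside the 20 Hz kinetic filter passband so the embedded peak
survives the extraction pipeline — the generator's contract is that
`extract_summary()` recovers embedded AICA, AROM, PVGRF, peak moments and
PAIA within 1% on noiseless trials, which the suite verifies over random
rows. The ACL elongation trace is a smoothstep to a peak strain found by
root-solving the *full discrete pipeline* (same strain-rate estimator,
same stress evaluation) so that the extracted peak ACL force matches the
row's PAF essentially exactly. Trial-level TED is whatever the moment and
angle templates imply; TED is calibrated at the summary level only.
Synthetic EMG is band-limited white noise amplitude-modulated by
raised-cosine burst envelopes.

What the generator does *not* emulate: soft-tissue artefact and marker
noise, bimodal or asymmetric GRF transients, frontal-plane energy
dissipation, trial-to-trial waveform shape variation (noise is added to
summary scalars and optionally as white measurement noise), and any
forward-dynamic consistency between force and motion. Passing round-trip
and calibration tests therefore demonstrates internal consistency of the
pipeline under the published summary statistics, not validity on new
laboratory data.

```{r example}
cohort <- generate_summary_cohort(cohort_config(), seed = 17)
su <- cohort$subjects
r_acl <- standardize_risk(su$PAF)
r_las <- standardize_risk(su$PAIA)
risk_intersection(su$AICA, r_acl, r_las)
balanced_range(su$AICA, r_acl, r_las)
```

## Problem sizes used in the checks

The test suite and the acceptance script run the generator at the study
condition (60 subjects × 5 trials) and average estimates over 200
replicate cohorts; constitutive-model checks compare against a
$10^6$-node trapezoidal oracle on a 20 × 5 grid of strain/strain-rate
pairs; waveform round-trips sweep 100 random summary rows. These sizes
give replicate-mean standard errors an order of magnitude below the
stochastic tolerances being checked.

## Known limitations

* The knee-flexion → ACL-elongation mapping is simulation-borne and never
  published in closed form; `acl_elongation_from_knee_flexion()` exposes
  it as explicit polynomial configuration and asserts no physiological
  default. Trials carrying a measured elongation channel bypass it.
* The fibre-orientation assumption (mean collagen axis parallel to the
  load) is a fixed modelling assumption with no runtime representation.
* Only short-term viscoelasticity is modelled — no creep, relaxation
  history, or stretch–shortening asymmetry.
* The calibration describes a male cohort; the published material
  constants sit oddly against the physiological strain caps (see the
  ligament section) and are reproduced, not endorsed.
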