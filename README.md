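# landrisk

Biomechanics of single-leg drop landings and the trade-off between
anterior cruciate ligament (ACL) injury risk and lateral ankle sprain
(LAS) risk.

Landing on one leg loads the limb with several body weights inside a few
hundred milliseconds. How the ankle is configured at touchdown — the
plantarflexion angle at initial contact (AICA) and the sagittal range of
motion during absorption (AROM) — changes where that energy goes: flat,
stiff landings raise the peak vertical ground reaction force (PVGRF) and
the peak ACL force (PAF), while plantarflexed, large-excursion landings
dissipate more energy but drive the ankle toward the inversion angles
(PAIA) associated with lateral sprain. `landrisk` implements the complete
analysis chain for studying this trade-off, for researchers in
musculoskeletal biomechanics and sports medicine:

* **Viscoelastic ACL model** — collagen fibres recruit sequentially with
  strain following a Weibull distribution (shape α = 4.5, scale β = 0.3);
  each recruited fibre carries elastic stress `K(ε − ε_s)` (K = 70 MPa)
  plus viscous stress `η ε̇` (η = 20 MPa s), giving the nominal axial
  stress

  σ_af(ε, ε̇) = ∫₀^ε w(ε_s) [K(ε − ε_s) + η ε̇] dε_s,

  zero in slack, with force F = σ_af · A summed over the anteromedial and
  posterolateral bundles (`nominal_axial_stress()`, `ligament_force()`,
  `acl_force_trace()`, `strain_limit_check()`).
* **EMG → activation** — band-pass (10–400 Hz), rectification, 6 Hz
  envelope, MVC normalisation, then the stable second-order recursion
  `u(t) = α e(t−d) − β₁ u(t−1) − β₂ u(t−2)` (α = 1 + β₁ + β₂) and the
  nonlinear shape function `a = (e^{Au} − 1)/(e^A − 1)`
  (`preprocess_emg()`, `neural_activation()`, `muscle_activation()`).
* **Landing metrics** — phase detection (VGRF > 10 N to maximum knee
  flexion), zero-phase Butterworth filtering (10 Hz kinematic / 20 Hz
  kinetic), joint power and sagittal energy dissipation, 101-point time
  normalisation, and the per-trial summary scalars
  (`detect_landing_phase()`, `extract_summary()`).
* **Risk statistics** — Pearson correlation with regression, min–max risk
  standardisation, the crossing of the fitted ACL-risk and LAS-risk lines,
  and the balanced-risk predictor interval (`pearson_with_regression()`,
  `standardize_risk()`, `risk_intersection()`, `balanced_range()`).
* **Synthetic cohorts** — a generator calibrated to the published cohort
  summary statistics (60 subjects × 5 trials), producing both summary
  tables with the published means/SDs/correlations and trial-level
  waveforms whose extracted summaries recover their generating parameters
  (`generate_summary_cohort()`, `generate_trial_waveforms()`,
  `generate_emg()`).

## Worked example

```r
library(landrisk)

# a calibrated synthetic cohort: 60 subjects x 5 landing trials
cohort <- generate_summary_cohort(cohort_config(), seed = 17)
su <- cohort$subjects

# correlation of ankle motion pattern with injury-risk markers
pearson_with_regression(su$AICA, su$PVGRF)
#> <correlation_result> r = -0.519 (R^2 = 0.269), p = 2.14e-05, n = 60
#>   regression line: y = 56.61 + -0.5766 x

# standardized risk trade-off between ACL injury and lateral ankle sprain
r_acl <- standardize_risk(su$PAF)
r_las <- standardize_risk(su$PAIA)
risk_intersection(su$AICA, r_acl, r_las)
#> <risk_intersection> crossing at predictor = 36.18
balanced_range(su$AICA, r_acl, r_las)
#> <balanced_range> [28.23, 44.14] about crossing 36.18 (tol 0.25)

# one synthetic trial pushed through the full landing pipeline
trial <- generate_trial_waveforms(as.list(cohort_calibration()$means))
round(as.data.frame(extract_summary(trial)), 2)
#>    AICA  AROM PVGRF  TED PADM PKFM PHFM  PAIA PAIM   PAF
#> 1 33.38 59.88 36.64 4.13 1.61 3.13 1.58 14.16 0.75 14.72
```

Reading the output: in this cohort a larger plantarflexion angle at
contact goes with a smaller mass-normalised impact peak (r = −0.52 here;
the calibrated population value is −0.591 and single-cohort estimates
scatter around it). The standardized ACL-injury and ankle-sprain risk
lines cross at ≈36° of AICA, and within roughly 28–44° the two fitted
risks differ by no more than 0.25 on the standardized scale — the
"balanced" ankle strategy. The extracted trial summary reproduces the
values embedded by the waveform generator (AICA 33.47°, AROM 59.99°,
PVGRF 36.61 N/kg, PAIA 14.19°, PAF 14.72 N/kg) to within the pipeline's
filtering tolerance; the trial-level TED is whatever the waveform
templates imply, since TED is calibrated at the summary level.

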