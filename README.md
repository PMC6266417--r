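# cyclemetrics

Analysis toolkit for repeated-measures studies that track balance,
proprioception and body composition across the menstrual cycle. It is aimed
at movement scientists who test a small panel of athletes many times over
one cycle (the reference design is 9 subjects, 12–14 sessions each) and
need three bespoke measurement procedures plus the longitudinal model that
ties them together:

1. **Joint-position-sense (JPS) scoring from images.** Subjects reproduce a
   target pose with closed eyes — trunk vertical, a 90° angle between upper
   arm and trunk and 90° between forearm and upper arm. From a frontal-plane
   image the package isolates the subject (grayscale + Canny edges), fits
   each limb's axis as a regression line through the midpoints of its outer
   edges, builds the longitudinal body axis from the waist midpoint and the
   inter-thigh midpoint, and reports the angles α (forearm/upper arm),
   β (upper arm/body axis) and γ (body axis/vertical) per body side,
   together with their absolute deviations from the 90/90/0 target.
2. **Dynamic postural control from perturbation trials.** From a 50 Hz
   platform displacement trace with a known perturbation onset it derives
   the four standard parameters: *threshold* (maximum x-excursion in the
   final 7 s of the 20 s test period, about the settled baseline), *time*
   (from perturbation until the oscillation permanently decays inside the
   threshold band), *distance* (path length of the curve up to that point,
   per axis) and *area* (rectified integral of the excursion, per axis),
   with medial/lateral trials averaged per leg and legs averaged per
   subject.
3. **A biquadratic random-coefficient mixed model over the cycle.** Test
   dates are allocated to cycle days t ∈ {1..28} (day 1 = onset of menses)
   and each outcome y for subject i at session m is modelled as

   y_im = Σ_{k=0}^{4} (β_k + b_ik) t'^k + ε_im,   t' = (t − 14.5)/13.5,

   with diagonal random-coefficient covariance, fitted by REML. The
   combined F-test of H₀: β₁ = β₂ = β₃ = β₄ = 0 decides between a
   time-dependent and a constant model; a Pearson screen correlates
   balance, proprioception and body-water variables across all pooled
   sessions.

Because studies of this kind rarely deposit raw recordings, the package
ships a synthetic-data module that emulates all three inputs with known
ground truth — rendered silhouettes with exact pose angles, damped-sinusoid
perturbation traces with closed-form envelopes, and longitudinal study
tables with configurable cycle-day effects and measurement noise at
realistic coefficients of variation — so the entire pipeline is testable
end to end.

## Worked example

```r
library(cyclemetrics)

# --- JPS: render a pose, recover its angles -------------------------------
img <- generate_silhouette(pose_params(alpha_left = 80, alpha_right = 100,
                                       beta_left = 95, beta_right = 85,
                                       gamma = 3))
res <- extract_jps(img)
res$angles
#> <arm_angles alpha=(79.72, 100.31), beta=(95.21, 84.75), gamma=2.98 deg>
```

The extractor recovers the rendered pose to a fraction of a degree; the
deviations from the 90/90/0 target are `dev_alpha = 10.3`, `dev_beta = 5.2`
and `dev_gamma = 3.0` degrees (the mean over sides of |α − 90| and
|β − 90|, and |γ|). `annotate_jps(img, res, "overlay.png")` writes the
overlay with the fitted axis lines and midpoint stars.

```r
# --- balance: score one perturbation trial --------------------------------
tr <- generate_balance_trace(balance_sim_params(amplitude = 10, damping = 0.4,
                                                freq = 1.5, noise_sd = 0.05,
                                                seed = 42))
balance_metrics(tr)
#>    leg direction threshold time distance_x distance_y area_x area_y settled
#> 1 left    medial     0.172 11.2        157        100   15.7   9.47    TRUE
```

A threshold of 0.172 platform units is the residual sway in the regained
balance phase; the oscillation decays into that band 11.2 s after the
perturbation, having travelled 157 units in x with a rectified area of
15.7 unit-seconds.

```r
# --- cycle model: plant a 0.01 l/day trend on extracellular water ---------
d <- generate_cycle_dataset(study_design(seed = 8),
                            default_study_effects(ecw_slope = 0.01))
fit_cycle_lmm(d, "ECW")$test
#> Combined test of time-dependent terms: F(4, 112) = 54.56, p = 1.916e-25
#>   verdict: time-dependent
```

With the trend set to 0 the same call returns a constant-model verdict.
`run_pipeline(pipeline_config(seed = 1))` chains everything — study table,
one scored silhouette and four scored perturbation trials per session,
per-outcome mixed models, the correlation screen and two-day binned means —
into one reproducible report bundle.

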