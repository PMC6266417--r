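---
title: "Measurement models and design choices in cyclemetrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measurement models and design choices in cyclemetrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyclemetrics)
```

cyclemetrics implements three measurement procedures for repeated-measures
cycle studies — image-based joint-position-sense (JPS) scoring,
perturbation-response balance metrics, and a biquadratic random-coefficient
mixed model — together with a synthetic-data module that makes the whole
chain verifiable without access to raw recordings. This vignette explains
each model, the parameters that matter, the numerical choices, and what the
synthetic validation does and does not establish.

## 1. Joint-position-sense scoring from silhouette images

### Measurement model

The target pose is trunk vertical (γ = 0), upper arms at β = 90° from the
longitudinal body axis, forearms at α = 90° from the upper arms. The
extraction chain is deliberately classical, requiring no markers and no
learned components:

1. grayscale conversion and binarization at the mid-intensity threshold;
2. Canny edge detection (Gaussian blur, Sobel gradients, non-maximum
   suppression, hysteresis);
3. per-limb *midpoint regression*: scan lines perpendicular to the
   expected limb direction are intersected with the edge map; a scan line
   that crosses exactly one limb yields two edge crossings whose midpoint
   lies on the limb axis (exactly so for a constant-width limb), and a
   least-squares line through the midpoints gives the axis orientation;
4. the longitudinal body axis is the line through two points: the midpoint
   of the upper body at waist height (the row of minimum torso width) and
   the midpoint between the thighs close to the knees;
5. angles are differences of line orientations. Fitted lines are
   undirected, so they are oriented anatomically before differencing (body
   axis up, upper arms pointing laterally, forearms pointing up); α is the
   interior elbow angle between the forearm direction and the
   elbow-to-shoulder direction, which preserves the full (0°, 180°) range.
   γ is reported unsigned — the target is zero deviation from the
   gravitational axis, so only the magnitude is meaningful. α- and
   β-deviations are averaged over body sides (per-side values are kept),
   matching one reported number per angle while analyzing sides separately.

### Scan-line geometry and windows

Upper arms in this pose are near horizontal, so they are scanned along
image *columns*; forearms are near vertical and are scanned along *rows*.
Search windows come from a body-proportion prior (`body_proportions()`),
anchored on mask landmarks (feet row, estimated body height h, torso
centre): upper arms are sought 0.17–0.245 h lateral of the body centre in
the band 0.68–0.885 h above the feet, a region where geometric analysis of
the working pose range (α, β ∈ [70°, 110°], |γ| ≤ 5°) shows no other body
part can appear; forearm windows are anchored at the elbow, estimated as
the point on the fitted upper-arm axis at the expected lateral distance,
which is nearly pose-invariant because the upper-arm length projects almost
entirely laterally over the working β range. Edge crossings close to the
upper-arm axis are excluded from the forearm scan so that poses whose
forearm leans over the upper arm do not contaminate the fit.

Two filters make the midpoint set robust. Scan lines with a number of edge
crossings different from two are skipped and counted. Lines whose edge-pair
separation deviates from the median by more than 6% are also dropped: a
clean cross-section of a constant-width limb has constant separation up to
subpixel noise (≈1%), while scan lines clipping a joint, an overlap or the
square end cap of a limb deviate far more — the tight tolerance is what
keeps end-cap cross-sections, whose midpoints sit off-axis, out of the
regression.

### Numerical choices

* **Subpixel localization.** Edge crossings are detected on the Canny map
  but localized by linear interpolation of the grayscale profile at the
  binarization threshold. With 2× supersampled (antialiased) rendering this
  gives midpoint noise well below 0.5 px, and line orientations good to a
  few tenths of a degree over limb baselines of 30–60 px.
* **Non-maximum suppression.** Gradient-direction neighbours are sampled
  with bilinear interpolation rather than 45°-quantized offsets, and the
  comparison carries a 3% relative tolerance. Both are needed on
  antialiased oblique edges: quantized NMS erases clean diagonal edges
  whose magnitude ridge straddles two pixels, and strict comparison erases
  two-pixel plateaus whose interpolated neighbour is marginally larger.
  The tolerance thickens edges to at most two pixels, which the
  crossing-clustering (gap ≤ 2 px) absorbs.
* **Canny thresholds.** Automatic: high = 25% of the maximum gradient
  magnitude, low = 40% of high. For the high-contrast images this module
  targets, the choice is uncritical; both are exposed for photographs.
* **Degenerate inputs.** An image without figure/background contrast is a
  "no subject detected" error; a window yielding fewer than two usable
  midpoints is a "segment not resolvable" error naming the segment.

### Renderer

The synthetic silhouette is a filled polygon figure — head, neck, waisted
torso, two legs, and arms with constant-width upper-arm and forearm
segments — rather than a photorealistic human. The extraction problem it
poses is exactly the one the measurement chain solves (edges → midpoints →
regression lines), and constant limb widths make the ground truth
analytically exact. The whole figure is rigidly tilted by γ, so the body
axis defined by the waist and thigh-gap midpoints carries the exact tilt.
The figure is centred on the pixel grid, so a symmetric pose renders a
bit-exact mirror-symmetric image. Geometry that would leave the frame is an
explicit error, never silent cropping.

Validation: across 50 random poses per seed in the working range, recovered
angles stay within 2° of ground truth with a mean error around 0.1–0.15°
(the acceptance suite enforces max ≤ 2°, mean ≤ 1°). What this does *not*
show: robustness to clothing, occlusion, uneven lighting, or background
clutter of real photographs — the pipeline assumes the subject is the only
high-contrast object and that limbs do not cross the torso or each other
beyond the working pose range.

## 2. Perturbation-response balance metrics

A trial is a 50 Hz two-channel (x, y) displacement trace with a recorded
perturbation onset inside the first 5 s and a 20 s test period after it.
The four metrics:

* **threshold** — maximum |x − x̄_w| over the final 7 s of the test period
  (the regained-balance window), where x̄_w is the mean over that same
  window. Measuring excursion about the settled-window mean, not raw zero,
  makes all metrics invariant to the arbitrary offset of
  accelerometer-derived displacement.
* **time** — "reaching the threshold" is implemented as *settling with
  permanence*: the first sample at or after the post-perturbation
  excursion peak from which the excursion stays inside the threshold band
  through the end of the test. A first-crossing reading (time until the
  rising flank first reaches the threshold value) would be trivially
  small on any perturbation response; it is still computed behind
  `mode = "first-crossing"` for sensitivity analysis. A trace exceeding
  the band at the last sample gets time = 20 s and an `unsettled` flag.
* **distance** — total variation Σ|s_{i+1} − s_i| of the chosen channel
  between perturbation and settling. Pure signal path length is used
  rather than arc length in the (t, s) plane, which would mix units; the
  two differ only by a monotone reparametrization of the same comparison.
* **area** — trapezoidal integral of the rectified excursion
  |s(t) − baseline| over the same window, so oscillation half-waves
  accumulate instead of cancelling; a signed variant sits behind a flag.

Medial and lateral trials are averaged per leg and the two legs averaged
per subject; missing (leg, direction) pairs are an error listing the gaps.

The trial simulator produces quiet-stance Gaussian noise until the
perturbation and a single damped sinusoid
A·exp(−λτ)·sin(2πfτ) plus noise afterwards, with the y channel a scaled
copy with independent noise. One damped mode matches the qualitative shape
of a platform released from a lever perturbation and gives closed-form
oracles (the envelope bounds the response; settling time ≈ ln(A/θ)/λ).
Against brute-force oracles evaluated on a 10×-oversampled grid over a
3×3×3 grid of (A, λ, f), all four metrics agree within 2% (measured worst
case ≈ 0.3%). Real platform data with multiple vibration modes,
drift, or re-perturbation artefacts are outside what this validates.

## 3. Cycle-day allocation and the random-coefficient model

### Day allocation

Test dates are allocated retrospectively: day 1 is the onset of menses and
day 28 the day before the next onset. For an observed cycle of length
L ≠ 28 the raw day d is linearly rescaled, day = round(1 + (d − 1)·27/(L − 1)),
which pins both endpoints and spreads interior days evenly; a truncation
variant (cap at 28) is available. Rescaling is the default because it
preserves the relative cycle position that the polynomial model consumes.
A test date outside any recorded cycle is an error rather than a guess.

### Model

For outcome y of subject i at allocated day t, with t' = (t − 14.5)/13.5,

y_im = Σ_{k=0}^{4} (β_k + b_ik) t'^k + ε_im,  b_ik ~ N(0, σ²_k) independent,
ε_im ~ N(0, σ²_e).

Choices worth stating:

* **Day scaling.** Raw day powers reach 28⁴ ≈ 6.1×10⁵ and ruin the
  conditioning of the normal equations; t' maps days 1..28 into [−1, 1] so
  all five basis columns are O(1). Coefficients are mapped back to the raw
  day scale for reporting through the triangular basis-change matrix, and
  the round trip reproduces fitted values to ~10⁻⁹.
* **Diagonal random-effect covariance.** With 9 subjects an unstructured
  5×5 covariance (15 parameters) is not identifiable; one variance per
  polynomial order is the largest structure the design supports.
* **Random intercept included.** The subject-level constant b_i0 is part
  of the default model (between-subject level differences are the dominant
  variance source in body-composition outcomes); `re_orders` drops it in
  one argument.
* **REML.** Variance components are estimated by maximizing the restricted
  likelihood with `nlminb` on the log-variance scale (bounded, so boundary
  estimates are flagged rather than fatal), starting every component at
  10% of the outcome variance; fixed effects are then generalized least
  squares at the optimum. Per-subject likelihood terms use the Woodbury
  identity on subject cross-products, so an evaluation costs one 5×5
  factorization per subject regardless of session count — which is what
  makes 500-replicate calibration runs cheap. The fit is deterministic
  given the data. An independent implementation (lme4 with independent
  per-order random terms) reproduces the coefficients, their standard
  errors and the REML criterion to at least four significant digits on
  simulated data.
* **Combined test.** H₀: β₁ = β₂ = β₃ = β₄ = 0 is tested with
  F = β̂'C'(CΣ̂C')⁻¹Cβ̂/4 from the GLS covariance, with denominator df
  n − 5 (residual df). No Satterthwaite or Kenward–Roger correction is
  attempted; instead the test's operating characteristics are measured
  directly: on the 9-subject, 13-session null design the empirical type-I
  error over 500 replicates sits near 0.03–0.04 at nominal 0.05, inside
  the 0.02–0.09 acceptance band, and power against a 5-residual-SD/day
  linear trend is 1. The verdict is "time-dependent" iff p ≤ 0.05.
* **Degenerate designs.** Fewer than five distinct days (or a
  rank-deficient basis) is an error naming the deficient column; in the
  no-random-effects limit the fit equals pooled OLS to ≥ 8 significant
  digits, and on exact quartic data it interpolates the coefficients to
  ≥ 6 significant digits (that check is run without random effects:
  at the σ² → 0 boundary the Woodbury difference loses precision to
  catastrophic cancellation, which is a property of the limit, not of the
  estimator at interior optima).

Descriptive companions: per-subject relative deviation statistics
(mean over sessions of |value − subject mean|/subject mean, summarized
across subjects plus the maximum single-session deviation — for Gaussian
noise with coefficient of variation c the folded-normal prediction
√(2/π)·c is recovered within 15% at 100-subject scale), and two-day binned
means over days {1–2, …, 27–28} with empty bins reported as missing.

### Study-table generator

Each subject enters the study at a random cycle point, is tested on 12–14
distinct cycle days, and outcomes are baseline + subject effect +
cycle-day effect + multiplicative noise (SD = cv × subject baseline). The
default outcome set uses instrument repeatability figures as within-subject
coefficients of variation — body mass 0.1%, skeletal muscle 0.4%, total
body water 1.0%, intracellular water 0.3%, extracellular water 0.4% — and
baselines consistent with a squad of trained female athletes (61 kg body
mass, 44.4% muscle and 20.3% fat fractions, with body water split into
compartments). Fat mass has no published instrument figure; its default of
4.8% is back-derived from an observed 3.8% mean individual deviation via
the folded-normal relation. Cycle effects are `none` by default (a null
study), with linear (e.g. the 0.01 l/day extracellular-water trend
scenario) and sinusoidal shapes available. The generator emulates
measurement repeatability and smooth cycle trends; it does not model
hormone pharmacokinetics, training- or diet-induced drift, or
device-specific electrode physics.

## 4. Correlation screen

All pairs between a balance group and a proprioception/body-water group
are correlated with Pearson's r over observations pooled across subjects
and sessions, with the two-sided p from the t transform on n − 2 df and no
multiplicity correction — the number of tests is attached to the result so
readers can judge the screen for what it is. Pooling ignores the
repeated-measures structure and therefore overstates the effective sample
size; a per-subject-mean variant (`by_subject_mean = TRUE`) is provided
for sensitivity. Zero-variance inputs and n < 3 are errors; missing values
are pairwise-deleted.

## 5. Pipeline and reproducibility

`run_pipeline()` chains the stages — study table, one rendered and scored
silhouette per session, four simulated and scored perturbation trials per
session, merge on cycle day, per-outcome mixed model with combined test,
correlation screen, two-day binned means — and writes plain CSV/JSON
artifacts plus a stage log, so each stage can be re-run and audited
independently. Every stage derives its random stream from one master seed;
identical configuration and seed reproduce the report bit for bit. Any
stage failure halts with the stage name. On a fully null configuration the
expected outcome is a constant-model verdict for (nearly) every outcome,
the negative-findings pattern this study design is built to detect.

Problem sizes used in the shipped verification: 50-pose recovery sweeps; a
27-cell balance oracle grid; 500 null and 200 planted-effect replicates of
the 9 × 13 study design for test calibration; 100 subjects for
stress-scale recovery checks. These sizes give Monte-Carlo error
comfortably below the acceptance bands while keeping the full suite in the
minutes range on one CPU.

## Known limitations

* The JPS extractor is specified for the arms-raised target pose on
  single-person, high-contrast images; poses far outside
  α, β ∈ [70°, 110°] or |γ| > 5° can defeat the window priors before the
  regression machinery ever sees the limbs.
* The settling-time reading of "reaching the threshold" is one of two
  defensible interpretations; both are computed, and the choice matters
  for absolute time values (first crossing is near zero by construction).
* The combined test relies on residual denominator df; with 9 subjects
  its size was verified by simulation rather than derived, and transferring
  it to very different designs should repeat that calibration.
* Pooled correlations are a screen, not inference under repeated measures.
* Cycle-length rescaling assumes the biological cycle stretches uniformly,
  which is a convention, not a physiological claim.
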