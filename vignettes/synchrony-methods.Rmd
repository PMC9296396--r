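---
title: "Quantifying interpersonal movement synchrony: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying interpersonal movement synchrony}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadsync)
```

## The measurement problem

Two people in conversation coordinate their body movement in time, and the
degree of that coordination — interpersonal synchrony (IPS) — carries
clinically relevant signal, for example in diagnostic interviews where
reduced synchrony accompanies autism-spectrum conditions. dyadsync measures
IPS from statically framed video in three stages: motion-energy extraction,
windowed lagged cross-correlation, and a surrogate-pairing null that
separates genuine coordination from coincidence. Because the clinical videos
such analyses are developed on cannot be shared, the package ships a
synthetic-data generator with known ground truth; every stage is validated
against it.

## Motion energy

Under a fixed camera, any change in grayscale pixel values inside a region
of interest (ROI) covering a person indicates that person's movement. For
consecutive frames the motion energy of a ROI is the number of pixels whose
absolute grayscale difference strictly exceeds a threshold
(`me_config(threshold = 15)`, on the 0–255 scale). The threshold absorbs
sensor noise and lighting flicker; 15 is a deliberately permissive default
for well-lit indoor recordings and should be raised if a static scene still
produces nonzero energy. Two conventions exist for the per-frame value:
counting super-threshold pixels (our default — bounded by ROI area and
matching the "frames with above-threshold movement" reading used for the
movement-quantity covariate) or summing their absolute differences
(`value = "sum"`). Downstream synchrony is Pearson-correlation-based and
thus invariant to monotone rescaling, so the choice does not propagate into
IPS; the package tests assert the scale-invariance directly.

ROIs are axis-aligned rectangles in 0-based `(x, y)` = (column, row)
coordinates, half-open, fixed for the whole recording; head and upper-body
ROIs of one person must be disjoint so that their energies are additive and
a person's total-body series is simply their frame-wise sum
(`total_roi_series`). Person detection, tracking and camera-motion
compensation are out of scope: the method presumes a static camera, and
`extract_series` performs no registration.

## Synchrony

Motion-energy series are nonstationary — people move in bouts — so
synchrony is computed locally: within moving windows of `window_s = 60`
seconds, advanced by `step_s = 30` seconds (50% overlap), series A is
correlated with series B shifted by every lag on a grid spanning
±`max_lag_s = 5` seconds. A positive lag pairs `A[t]` with `B[t + lag]`,
i.e. B trailing A. Three numerical choices matter:

* **Truncated overlap.** A lag-ℓ cell correlates the `window − |ℓ|` frame
  pairs that remain inside the window; no wraparound or zero padding, which
  would manufacture artifactual correlation at the window edges.
* **Zero-variance windows are missing, not zero.** If either segment is
  constant, Pearson r is undefined. Coding such cells as 0 would drag the
  aggregate toward zero exactly in the low-movement passages where the
  estimate is least informative; they are `NA` and excluded from
  aggregation, with `min_valid_cells` guarding against an all-missing dyad.
* **Clipping before the Fisher transform.** Correlations are clipped to
  ±(1 − 10⁻⁷) before `atanh`, so the degenerate perfect correlations that
  synthetic identity cases produce stay finite (≈ 8.41) instead of infinite.

Each r is Fisher-Z transformed (variance-stabilising, so means over cells
are meaningful) and IPS is the mean of |z| over all defined window-by-lag
cells. Absolute values are taken *after* the transform; in-phase and
anti-phase coordination count alike, and IPS ≥ 0 with equality only when
every defined correlation is exactly zero. Swapping the interactants mirrors
the lag axis and leaves IPS unchanged.

The stride (30 s) and the lag grid resolution (1 frame, i.e. 0.04 s at
25 fps, 251 lags across ±5 s) are documented package choices where the
method family's published descriptions are silent; both are configurable in
`sync_config`, and the calibration experiments below use a coarser 0.5 s
lag grid for speed. When a recording must be split (e.g. an interruption
mid-session), IPS is computed per part and averaged with equal weight
(`combine_split_vignette`).

## The pseudosynchrony null

An IPS value is meaningless in isolation: windowed |r| is positive even for
independent series. Chance level is estimated by re-pairing series of
people who never interacted. With V recordings of two interactants each,
the eligible pool is every unordered pair of pooled series minus the V
genuine pairs — `choose(2V, 2) − V` pairs (3,120 for V = 40). This
all-non-interacting-pairs rule is an inference from that published pool
size; a role-restricted rule (only patient-with-clinician re-pairings)
would give a different count and is not the default. `n_draws` pairs
(default 1,000) are sampled uniformly *without replacement* — the draws are
distinct pairings — and pushed through the identical synchrony pipeline,
truncating unequal-length pairs to their common length. Genuine synchrony
is then tested one-tailed (real > pseudo) with the Mann–Whitney U test.

## Group statistics

The battery mirrors standard practice for small clinical samples. Normality
is gated per group with Shapiro–Wilk at α = 0.05: if either group departs,
the Mann–Whitney test is used, otherwise the pooled-variance Student t-test
(the pooled form, not Welch, is what published df = n1+n2−2 values imply;
this rule-by-example is documented as an inference). Mann–Whitney p-values
come from exact enumeration of all group assignments when n1+n2 ≤ 12
(valid under ties) and from the tie-corrected normal approximation with
continuity correction otherwise. Effect sizes are Cohen's d with pooled SD,
also attached to U tests for comparability. Missing questionnaire scores
are imputed with the observed mean of the participant's own group — a
mean-preserving, flagged imputation. IPS–questionnaire associations default
to Spearman rank correlation: the published analyses do not name their
method, and the bounded, often skewed score scales argue for ranks; Pearson
is available as an option. One-tailed directions are never implicit — every
hypothesis states its tail in the call.

## The synthetic-data generator

Real motion-energy traces are nonnegative, zero-inflated and strongly
autocorrelated: movement comes in multi-second bouts separated by
stillness. The generator mimics this with a latent burst-driven AR(1)
process per interactant,

x_t = φ x_{t−1} + B_t E_t,  B_t ~ Bernoulli(burst_rate),  E_t ~ Exp(burst_scale),

with φ = 0.95, burst_rate = 0.05 and burst_scale = 10 by default (bouts a
few seconds long at 25 fps, arriving about every second of active
conversation). Coupling is linear mixing before observation: interactant
B's latent signal is `(1 − c)` times its own process plus `c` times A's
process shifted by `lag_frames`. Gaussian measurement noise
(`noise_sd = 1`) is added and the result rectified at zero. This is the
simplest mechanism that yields a tunable windowed cross-correlation with a
controllable lag; `c = 0` gives independent interactants, and `c = 1` with
zero lag and noise reproduces A exactly. Seeds are explicit arguments
everywhere — the generator never touches the caller's RNG stream.

The latent model is a stand-in for the statistical *shape* of clinical
traces, not a claim about them: passing tests demonstrate that the pipeline
recovers known coupling, lag and null behaviour from data with realistic
marginal structure, not that it behaves identically on any particular
clinical population. Features of real data the generator does not emulate
include cross-ROI dependence within a person, slow nonstationarity
(fatigue, topic changes), and occlusion artifacts.

Cohorts (`cohort_spec`) default to the reference study's shape: 16 dyads in
the diagnosed group, 23 in the comparison group, 14-minute sessions at
25 fps, and questionnaire scores drawn from truncated normals using the
published group means and SDs at the instrument bounds (e.g. AQ on 0–50).
Truncation is the honest reading of a bounded instrument, with the side
effect that a group mean near a bound shifts slightly (the diagnosed-group
AQ mean shifts down by ≈ 0.4 points); generator checks therefore compare
against the analytic truncated-normal mean. The default group coupling
strengths (0.15 diagnosed vs 0.25 comparison, lag 12 frames) encode the
qualitative finding of reduced synchrony at a plausible sub-second lead;
they are starting points for simulation studies, not estimates.

Synthetic videos (`gen_synthetic_video`) render one bright square blob per
ROI on a static background; a blob jumps to the next of a set of disjoint
positions on each scheduled frame, so the scheduled fraction of moving
frames is the exact ground-truth movement quantity and each jump changes
exactly twice the blob area in pixels.

## Validation and problem sizes

The test suite validates each stage against an independent oracle: the
windowed cross-correlation matrix against a first-principles per-window,
per-lag loop (to 10⁻¹²); extraction against a per-pixel double loop;
Mann–Whitney U and its exact p against exhaustive enumeration of group
assignments; the pooled t against `stats::t.test(var.equal = TRUE)`.
Calibration batteries check the statistical behaviour end to end:

* **Null calibration** — 200 uncoupled dyads: real-pair IPS and
  pseudosynchrony must be indistinguishable (two-sample Kolmogorov–Smirnov);
  and over 500 simulated null cohorts of 16 dyads with 50 surrogate draws
  each, the one-tailed synchrony-vs-chance test must reject at its nominal
  5% rate.
* **Signal recovery** — mean IPS strictly increases over the coupling grid
  {0, 0.25, 0.5, 0.75, 1} (50 replicates each), and an injected +25-frame
  lag is recovered at the peak of the window-averaged |r| profile to within
  one frame at full 25 fps resolution.

The batteries simulate 120-second sessions at 10 fps with a 0.5-second lag
grid — sizes chosen so the whole battery runs in minutes on one CPU while
leaving several windows and dozens of lags per dyad; the lag-recovery check
alone keeps the full 25 fps single-frame grid, since it asserts frame-level
accuracy. `scripts/acceptance.R` re-runs all of them from scratch under a
caller-supplied seed.

## Known limitations

* No video-container decoding: input is frame arrays or PNG frame
  directories (plus pre-extracted series CSVs); decode MP4/AVI to frames
  upstream.
* Rectangular, fixed ROIs only; a person leaving their ROI or the camera
  moving violates the measurement model silently.
* IPS is symmetric by construction; leading-versus-following asymmetry,
  time–frequency measures and segment-shuffling null families are
  deliberately out of scope.
* The pseudosynchrony eligibility rule is an inference from published
  combinatorics (see above) and is configurable should role-restricted
  pairing be required.
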