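---
title: "Methods: synthetic gait EMG and multi-axial intent prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic gait EMG and multi-axial intent prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Controlling a powered below-knee (transtibial) prosthesis from muscle
activity alone requires predicting, window by window, which ankle-foot
motion the user intends: dorsiflexion at heel strike, foot flat in
mid-stance, plantarflexion at push-off, and — on uneven ground — the
frontal-plane motions eversion and inversion. Only three lower-leg muscles
are practical for surface recording on a residual limb: tibialis anterior
(TA), medial gastrocnemius (MG) and lateral gastrocnemius (LG). `emgintent`
implements this prediction problem end to end on synthetic data: a seeded
gait EMG generator, the standard conditioning chain, windowed time-domain
features, four classifiers, three prediction approaches, and a factorial
evaluation across electrode-placement and terrain conditions.

Because the original laboratory recordings behind this study design are not
publicly available, everything here runs on simulated data whose structure
matches the study conditions. Absolute accuracies on synthetic data are not
comparable to accuracies on laboratory data; the package's tests therefore
check *directional* findings (which condition or approach beats which), not
point values.

## The generative model

A trial is `n_steps` gait cycles of nominal duration 1.1 s (per-step
uniform jitter of ±3%), sampled at 2000 Hz. Each cycle is partitioned as:

| cycle fraction | label |
|---|---|
| 0.00–0.15 | 1 dorsiflexion (loading) |
| 0.15–0.42 | 2 foot flat |
| 0.42–0.62 | 3 plantarflexion (push-off) |
| 0.62–1.00 | 0 swing (sentinel, excluded downstream) |

On uneven terrain, each step independently receives a frontal-plane event
with probability `frontal_event_prob` (default 0.5): the central part of
mid-stance (fractions 0.20–0.38) is relabelled eversion or inversion,
alternating across event steps so both classes appear. Trials of at least
10 steps are guaranteed two event steps so that batch-level class coverage
is deterministic.

Each muscle's noise-free activation envelope is a raised-cosine bump per
labelled segment, with peak amplitude (fraction of MVC) taken from the
activation profile, times the walking-style gain, a per-participant
log-normal factor (sd 0.08) and a per-step log-normal factor (sd 0.05 level
ground, 0.12 uneven), plus a tonic floor of 0.02. The default profile
encodes the qualitative activation expectations that motivate the
deterministic rule classifier: TA maximal and MG minimal during
dorsiflexion; TA minimal and MG maximal during plantarflexion; TA maximal
with LG above MG during eversion and MG above LG during inversion.

The raw signal is `envelope × carrier × MVC`, where the carrier is zero-mean
Gaussian noise band-limited to 20–450 Hz (4th-order Butterworth, applied
forward-backward) and rescaled to unit standard deviation. Amplitude-
modulated band-limited noise is the standard desk-scale surface-EMG
generative model; it reproduces the spectral band and the envelope
statistics that the downstream pipeline consumes, and it is fully
deterministic under a seed.

Walking styles scale one muscle's envelope: hyper styles by 1.8, moderate
styles by 1.35 (six styles: hyper TA/MG/LG, moderate MG/LG, optimum).
These defaults keep styles separable from the optimum pattern while
overlapping with participant-level variability.

The electrode-shift (ES) condition replaces the displaced channel with
`0.6 × own + 0.25 × neighbour` (TA's neighbour is LG; MG and LG neighbour
each other). The displaced electrode sits over the participant's dominant
style muscle (MG for optimum-style walkers). ES trials are derived from the
*same* simulated walks as the optimally-placed (OE) trials, so the
comparison is paired and the electrode effect is isolated from gait
variability; a laboratory study would instead record separate walks.

What the simulator does **not** emulate: motion-artifact transients,
electrode-skin impedance drift, muscle fatigue, inter-muscle timing shifts,
co-contraction strategies, or the kinematic/kinetic side of gait. Passing
tests on this generator show that the pipeline recovers structure it is
designed to recover; they do not certify performance on laboratory EMG.

## Conditioning chain

1. **Band-pass 20–450 Hz**, Butterworth. The design order is not fixed by
   convention; the default is 4, configurable.
2. **Rectify and MVC-normalize.** Division is by each muscle's maximum
   voluntary contraction amplitude; the simulator writes the true MVC into
   the trial metadata, and `estimate_mvc()` (99.5th percentile of the
   rectified band-passed signal) is the fallback for external data.
   Rectification is performed inside this step: a 20 Hz low-passed,
   MVC-normalized signal is only meaningful as a linear envelope of
   rectified EMG, so the chain makes that explicit.
3. **Envelope low-pass**, 2nd-order Butterworth at 20 Hz; negative ripple
   clipped to zero.

"Recursive" filtering is read as causal single-pass application — the
real-time-compatible choice for a prosthesis controller; forward-backward
(zero-phase) application is available via `zero_phase = TRUE` for offline
analysis. Stage tags (`raw → bandpassed → normalized → envelope`) make
out-of-order or repeated filtering an error rather than a silent bug.

Note one consequence of rectification: the measured envelope is the true
envelope scaled by the carrier's mean absolute value (≈ 0.80 for unit-sd
Gaussian noise). All style and bias statistics are ratios, so this factor
cancels wherever it matters.

## Windows and features

The envelope stream is cut into sequential, non-overlapping 150 ms windows
(300 samples at 2 kHz); the trailing partial window is discarded. A window
takes the majority per-sample label; ties break toward the label whose run
starts earliest in the window (the tie rule is a package choice — no
convention exists for mixed windows). Swing-majority windows are dropped:
swing motion is not load-bearing and is excluded from prediction.

Per channel and window, six time-domain features (standard myoelectric-
control definitions, fixed here because the study design names the features
without printing formulas):

* `VAR = Σ(xᵢ − x̄)² / (n − 1)` (the n−1 denominator is configurable by
  recomputation; documented, not exposed as an option),
* `WL = Σ|xᵢ₊₁ − xᵢ|`,
* `IEMG = Σ|xᵢ|`,
* `MAV = IEMG / n` — "moving average" is read as the per-window mean
  absolute value, one value per window, consistent with per-window
  classification,
* `RMS = √(Σxᵢ² / n)`,
* AR(2) coefficients by Yule–Walker with biased autocovariances, in the
  convention `x_t = ar1·x_{t−1} + ar2·x_{t−2} + e_t` (deterministic, no
  iterative fitting).

With a fixed window length, `IEMG = n × MAV` exactly, so any feature mask
containing both makes the pooled covariance singular; the LDA handles this
(below) rather than silently dropping features, and the redundancy is
visible in the subset search.

`feature_subset_search()` evaluates all 63 non-empty feature subsets with
an LDA on a stratified, seeded 70/30 split and reports held-out accuracy.

## Classifiers

**Deterministic rule.** From the window aggregates `S_TA, S_MG, S_LG`
(sums of normalized envelope samples — the conditioned signal itself, not
features) and predicates `p: S_TA > S_MG`, `q: S_TA > S_LG`,
`r: S_MG > S_LG`: class 1 if `p∧q`; 3 if `¬p∧¬q`; 4 if `p∧¬r∧¬q`; 5 if
`q∧r∧¬p`; else 2. Ties use strict `>` as written, so equal aggregates make
predicates false. Two properties deserve emphasis:

* *The foot-flat branch is unreachable for real-valued inputs.* By
  transitivity, the only realizable predicate patterns map to classes 1, 3,
  4 and 5; every pattern that would reach "otherwise" requires a cyclic
  ordering of three real numbers. The rule therefore never predicts class 2,
  and true foot-flat windows land in the dorsiflexion column. The package
  implements the rule exactly as written and reports this behaviour in
  its confusion matrices rather than patching the rule.
* *The rule's branch conditions disagree with its own design expectations
  for the frontal-plane classes.* The generative profiles make TA maximal
  during eversion and inversion (the stated design expectation), but the
  eversion/inversion branches fire only when TA is the middle channel.
  Consequently classes 4 and 5 are also predicted as dorsiflexion on
  conformant envelopes. The simulator follows the design expectations; the
  classifier follows the printed branches; the mismatch is reported, not
  hidden.

**LDA.** Hand-implemented pooled-covariance Gaussian LDA (class means,
shrinkage-free pooled covariance, empirical priors), because the contract
requires behaviours a library fit does not expose: a ridge fallback on
singular pooled covariance (`1e-6 × mean(diag(Σ))`, escalating tenfold
until the Cholesky succeeds, with a message), deterministic tie-breaking
toward the lower class code, and JSON serialization of means, covariance
and priors. The test suite cross-checks predictions against an independent
reference implementation. The ridge is scale-relative rather than absolute
because the feature scales span many orders of magnitude (VAR of an
MVC-fraction envelope versus IEMG).

**CART.** Gini-impurity classification tree via `rpart`, cross-validation
disabled (`xval = 0`) so fits are deterministic; defaults `maxdepth = 8`,
`minbucket = 5`, both configurable.

**Voting.** If any two of (LDA, tree, deterministic) agree, the agreed
class wins; otherwise the deterministic output is used. This is a
single-instant vote across classifiers, not a vote over a classifier's past
decisions.

## Prediction approaches

* **Generic:** one (LDA, tree) pair on the pooled windows of all training
  participants; applied unchanged to new participants. A leakage guard
  errors if a test participant's windows reach a pool they trained.
* **Biased generic:** per-channel gains `ref_m / mean_m` (clipped to
  [0.25, 4]) computed from the test participant's level-ground stance
  envelopes move their data toward the optimum reference before
  featurization; then the generic models are applied. The deterministic
  aggregates stay unbiased — that classifier consumes raw conditioned
  signal, which is why its accuracy is identical across approaches.
* **Walking style:** training participants are grouped by their *identified*
  style and one model pair is fitted per represented style; a test
  participant's style is identified from their level-ground trials of the
  same electrode condition and routes them to that style's models, with the
  pooled models as fallback for unrepresented styles.

Style identification uses the relative deviation
`d_m = (mean_m − ref_m)/ref_m`: `hyper_<argmax>` if `max d ≥ 0.5`,
otherwise `moderate_<argmax over MG,LG>` if that deviation is ≥ 0.2,
otherwise optimum; ties resolve in TA, MG, LG order. The thresholds are
package choices matched to the simulator's default gains (deviations
concentrate near 0.8, 0.35 and 0 for hyper, moderate and optimum walkers);
there is no moderate-TA style, so sub-hyper TA deviations map to optimum.

Two reference constructions are provided. `style_reference()` averages the
optimum-style *training participants'* level-ground stance envelopes — the
only option when all data come from a small cohort, and the construction
used inside `run_experiment()`; with a single optimum participant it is
noticeably noisy, and style misidentification under that noise is visible
in the experiment output. `normative_reference()` instead simulates a long,
variability-free optimum walker in measured-envelope units — the analogue
of taking the optimum pattern from normative gait literature — and is the
appropriate reference for parameter-recovery checks.

## Evaluation design and problem sizes

`run_experiment()` evaluates the full 3 × 4 × 2 × 3 grid (approach ×
classifier × electrode condition × data set, the data sets being the
combined pool and the two terrain-decoupled slices). Accuracy is
trace/total of the pooled 5 × 5 confusion matrix (rows = true class);
per-class (macro) accuracy is reported alongside. Per-participant accuracy
vectors feed two-tailed paired t-tests (electrode condition, data set, and
pairwise approach/classifier comparisons) at α = 0.05 with no
multiple-testing correction — raw p-values are reported as in the original
analysis design.

Default problem sizes, chosen so the full factorial runs in well under a
minute on one core while every cell keeps hundreds of test windows: 6
training participants (one per walking style), 10 test participants
(round-robin styles; 10 rather than the original 3 so the paired t-tests
have stable denominators — set `n_test = 3` for the original design), 4
trials per participant and terrain, 10 steps per trial. Self-selected
walking speed is exposed as `speed_factor` but not used as an experimental
factor.

## Known limitations

* Absolute accuracies on synthetic data are far higher than on laboratory
  EMG: the generator's class-conditional envelopes are cleaner than real
  gait, and the ES degradation is a simple linear mixing. Only directional
  comparisons are meaningful.
* The deterministic rule's unreachable foot-flat branch (above) means its
  error structure on synthetic data concentrates in the dorsiflexion
  column, not the foot-flat column; this is a faithful consequence of the
  rule as printed.
* The style taxonomy is one-muscle-dominant by construction; mixed
  deviations (e.g. hyper MG *and* LG) are attributed to the larger one.
* The normative reference is itself simulated; with real data it should be
  replaced by published normative activation curves.
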