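---
title: "Predicting antidepressant treatment outcome from resting-state EEG: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting antidepressant treatment outcome from resting-state EEG: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`restpredict` implements a complete analysis pipeline for predicting
whether a patient with major depressive disorder will respond to an
antidepressant (escitalopram being the motivating case) from resting-state
EEG recorded at baseline and two weeks after treatment start. The outcome
is dichotomized from the clinician-rated MADRS scale (0–60): a *responder*
is a patient whose score decreased by at least 50% from baseline to week 8.
The pipeline is: multi-site cohort (real or simulated) → harmonization and
cleaning → four classes of EEG features → stability-voting feature ranking
→ RBF-kernel SVM classification evaluated with stratified k-fold and
leave-one-site-out cross-validation → a Monte Carlo bound on the accuracy
attainable given measurement noise in the outcome scale itself.

The multicenter EEG dataset that motivated this design is not publicly
deposited, so the package ships a synthetic-cohort generator with known
ground truth as a first-class module. All headline numbers produced by the
package are therefore *procedure-level* properties (calibration, recovery
of injected effects, oracle equivalences), not reproductions of any
clinical dataset's accuracy figures.

# Outcome labeling

`percent_decrease(b, w8)` is `100*(b - w8)/b`; `label_responder()` applies
the ≥ 50% rule. The boundary is read inclusively — a patient with exactly a
50.000% decrease is a responder. Published descriptions of such criteria
rarely state how exact-boundary cases are handled; we chose the literal
reading of "decreased by at least 50%" and test the boundary explicitly.
Subjects without a week-8 score have no defined label and are excluded from
all modeling.

# Synthetic cohorts

`generate_cohort()` emulates a 122-subject, four-site cohort
(52/45/18/7 subjects per site, ~45% responders, 7 of 122 lacking the
week-2 recording) with configurable sizes. Each channel is the sum of

* a 1/f background (spectral exponent ≈ 1), amplitude 3 (arbitrary µV-like
  units), the dominant broadband component;
* band-limited oscillators — theta 4–8 Hz (frontal-weighted), alpha
  8.5–12 Hz (posterior-dominant, the strongest rhythm), beta 12.5–21 Hz
  (central) — each a slowly amplitude-modulated sinusoid with a
  per-recording random carrier frequency; per-subject oscillator
  amplitudes are lognormal with SD 0.2 on the log10 scale;
* white sensor noise (SD 0.5) plus a per-site gain and additive noise
  floor (the site-effect model — instrument differences across sites are
  not characterized in the literature we build on, so a gain + noise-floor
  model is our own minimal choice).

Group effects are injected as `effect_spec` objects: band-power effects
scale the matching oscillator's amplitude for responders by
`10^(0.2 * d)`, which shifts the log10 band-power feature by about
`0.4 * d` against a between-subject feature SD of about 0.4, so the
realized standardized difference is close to the nominal `d` (verified by
Monte Carlo at n = 200 to within ±0.3). Entropy effects mix an AR(1)
component (coefficient 0.95) into responders' channels, lowering
low-scale sample entropy. Week-2 recordings reuse each subject's latent
amplitudes with fresh noise plus any week-2 effects, so *early change*
features have known ground truth.

MADRS trajectories are drawn per group from truncated normals — responders'
percent decrease centered at 73.3 (SD 16.0) truncated to [50, 100],
nonresponders at 20.4 (SD 21.6) truncated below 50 — and week-8 scores are
back-computed, so the ≥ 50% rule reproduces the intended assignment exactly
when the optional rater-noise SD is 0. Boundary-adjacent subjects are
allowed. Baseline scores are N(30.1, 5.8) truncated to [12, 50].

What the generator does **not** emulate: volume-conducted scalp
topographies from anatomical head models, ocular/muscle artifacts beyond
amplitude outliers, eyes-open/closed condition structure, or realistic
channel covariance. Passing tests on these cohorts demonstrates that the
*procedure* is correctly implemented and calibrated, not that any
particular accuracy is attainable on real patients.

# Preprocessing

`harmonize()` brings each raw recording to a common format: channels
reordered to the target montage, resampling by anti-alias low-pass (8th
order Butterworth at 0.8 × target Nyquist) followed by linear
interpolation onto the new time grid, then average reference.
`filter_line_noise()` is a zero-phase order-4 Butterworth band-stop at
±2 Hz around the line frequency; `bandpass()` an order-4 zero-phase
band-pass. Epochs are 2 s; epochs exceeding ±100 µV on any channel are
rejected, and subjects with fewer than 15 clean epochs (configurable) are
flagged for exclusion. Two band-passed copies are kept: 1–30 Hz for
spectral and microstate analysis and 0.5–55 Hz for entropy, because sample
entropy is sensitive to narrow filtering. The upstream study's exact
cleaning parameters are not public; every value here is a documented,
config-exposed stand-in.

# Feature classes

**Electrode-level spectra.** Welch PSD (2-s Hann-windowed epochs as
non-overlapping segments, 0.5 Hz resolution), integrated over seven fixed
bands: delta 1–3.5, theta 4–8, low alpha 8.5–10, high alpha 10.5–12, low
beta 12.5–18, middle beta 18.5–21, high beta 21.5–30 Hz. Absolute power is
log10-transformed before modeling (variance stabilization for the t-test
filter); hemispheric lateralization uses the bounded, scale-free
normalized difference `(L − R)/(L + R)` over eight homologue pairs of the
19-channel 10–20 montage.

**Source-space spectra.** An eLORETA inverse operator (fixed scalar
orientations) is computed from a leadfield by iterating the weight fixed
point `w_j = sqrt(k_j' (K W⁻¹ K' + αH)⁺ k_j)` to a relative tolerance of
1e-6 (cap 100 iterations), with `α` set to 0.05 of the mean eigenvalue of
`K K'`. eLORETA's defining property — exact localization of noiseless
point sources — is verified exhaustively on a 20 × 200 synthetic leadfield
in the test suite. Band power is averaged over sources within each ROI.
Real head models are out of scope; with the synthetic leadfield the
source features are labeled synthetic-anatomy.

**Multiscale entropy.** Sample entropy (`m = 2`, tolerance `r = 0.15` of
the scale-1 SD, held absolute across scales per the standard
coarse-graining convention) evaluated at 70 timescales of non-overlapping
block means. The `m`/`r` defaults are the standard values of the sample
entropy literature; they are config-exposed. MSE is computed on the
concatenated clean signal rather than per 2-s epoch, because coarse
graining a 500-sample epoch at scale 70 would leave ~7 samples; scales
whose coarse series is shorter than 100 samples are reported missing and
excluded feature-wise from ranking rather than imputed. Undefined
entropies (zero template matches) are returned as missing, never as
infinities. The counting kernel sorts templates by first coordinate so
only first-coordinate-compatible pairs are examined; results are
bit-identical to the O(n²) definition (tested).

**Microstates.** Polarity-invariant modified k-means (k = 4 by default)
on maps at GFP peaks, best of 10 restarts, topography update via the
dominant eigenvector of the assigned maps' outer-product sum. The model is
fitted at group level (pooled peaks across subjects) and back-fitted per
subject — group-level fitting keeps per-class features comparable across
subjects; a per-subject mode is available by passing single-recording
lists. Back-fitting assigns each sample by maximal squared spatial
correlation, merges segments shorter than 30 ms, and yields per-class mean
duration, occurrence, coverage, and the segment-level transition matrix.

# Feature sources and assembly

Features are tagged `baseline`, `week2`, or `early_change` (week-2 value
minus baseline value, the unqualified raw difference; a percent-change
variant would be a one-line config change but raw difference is the
default). The `combined` source is the column-wise union of baseline and
early-change features; subject sets are all subjects for baseline and the
week-2 subset otherwise. Standardization is deliberately *not* applied at
assembly: z-scoring is fitted on training partitions only, inside the
evaluation loops, to prevent leakage.

# Feature ranking

At each of 100 iterations, an 80% class-stratified subsample is drawn
without replacement and a Welch (unequal-variance) two-tailed t test is
run per feature; the feature earns a vote when p < 0.05. Votes 0–100 index
robustness of the group difference. The per-iteration α = 0.05 and the
Welch flavor are our choices (the upstream description leaves them open)
and are config-exposed. Selection keeps features with votes ≥ T (inclusive,
matching the "≥" convention of vote-threshold tables); T ∈
{50, 60, 70, 80, 90} is the standard grid and T = 60 the standard
leave-one-site-out choice. Under the null the vote rate calibrates to
about 100·α (tested over seeds), and label permutation collapses strong
features into the null band.

One property of this filter is worth knowing: votes are strongly
correlated across iterations, because every 80% subsample retains the full
sample's realized group difference. A null feature whose observed
difference happens to be large therefore collects many votes in *every*
iteration — the vote count measures stability of the observed difference,
not family-wise significance, and under the null roughly an α fraction of
features will pass even a high threshold. What is calibrated is the rate
(mean votes ≈ 100·α, tested), and what protects the final accuracy
estimates from this selection noise is recomputing the ranking inside
every training partition of the cross-validation.

# Classification and evaluation

RBF-kernel SVMs (libsvm via e1071) with class weights inversely
proportional to class frequencies. Hyperparameters are chosen by inner
stratified cross-validation maximizing balanced accuracy over
log2-spaced grids (defaults C ∈ 2^{−5..15}, γ ∈ 2^{−15..3}, step 2²,
inner 5-fold); the grids are config-exposed and the package's own tests
use reduced grids (3 × 3) with 3 inner folds, which we found sufficient
for the synthetic cohorts at desk scale. Outer evaluation is stratified
10-fold cross-validation; ranking, selection and scaling are recomputed
inside every training partition by default (`nested_ranking = TRUE`) —
the leakage-free protocol — with a non-nested mode for comparison.
Sensitivity, specificity and balanced accuracy (responder = positive) are
computed from pooled confusion counts; per-fold values are also reported.
When no feature reaches T inside a training partition (common under the
null), the single top-voted feature is used so the fold remains defined;
`select_features()` itself errors on empty selections.

`leave_one_site_out()` holds out each site in turn, trains on the rest
(ranking/selection/scaling/tuning on training sites only), and reports
per-site balanced accuracy with test-set sizes; a held-out site lacking
one class gets the undefined rate flagged rather than silently dropped.

# Label-noise accuracy ceiling

If the scores defining the labels carry measurement noise, even an oracle
that knows every true label scores below 100% against observed labels.
`estimate_ceiling()` treats the supplied baseline/week-8 scores as truth,
adds independent N(0, σ²) noise to the measured scores (both visits by
default; a week-8-only variant is selectable), re-derives observed labels
by the ≥ 50% rule, and scores the truth-emitting oracle against them,
averaging balanced accuracy over replicates with a percentile CI. This
oracle-predictor formulation is one defensible reading of "upper bound on
achievable accuracy"; σ and its placement are user inputs, deliberately
not estimated from any external test–retest literature. The ceiling is
100% at σ = 0, declines monotonically in σ (verified with common random
numbers), and approaches 50% as σ → ∞.

# Numerical choices and degenerate inputs

* Welch PSD uses the periodic Hann window; with 0.5 Hz bins an exact-bin
  sinusoid leaks only into adjacent bins, so an interior-band tone keeps
  ≥ 95% of 1–30 Hz power in its band (a band-edge tone keeps ~83%, the
  Hann mainlobe split — the leakage bound derivable from the window).
* Band integration uses bin sums × bin width, making disjoint bands
  exactly additive.
* Zero-power features are log-clamped at the smallest double; zero/zero
  lateralization and asymmetry are missing, not 0.
* The eLORETA pseudoinverse uses `MASS::ginv`; rank-deficient leadfields
  (rank < channels − 1) and non-convergence raise errors with
  diagnostics rather than returning a bad operator.
* Microstate label smoothing merges short segments sweep-wise with an
  oscillation guard and a strictly convergent single-merge fallback;
  ties between neighbour segments go left.
* k-means dead classes are reseeded at the worst-fitted map; fits are
  deterministic given the seed.
* Stratified folds deal shuffled class members round-robin, so every
  training partition keeps both classes whenever class counts allow.

# Problem sizes used by the shipped tests

The test suite and acceptance script exercise the EEG-level pipeline at
reduced sizes chosen to keep a full run comfortable on one CPU: cohorts of
6–30 subjects (with one n = 200 reduced-montage Monte Carlo for
effect-size recovery), 16–60 s recordings, 5–20 entropy scales for
EEG-level runs (the 70-scale default is asserted on single signals), and
feature-level cohorts of n = 120 × 200 features for ranking/classifier
calibration — the cohort scale at which the method is meant to operate.
These sizes are the package's own validation design; all are config
parameters, and nothing in the implementation depends on them.

# Known limitations

* The synthetic signal model is channel-independent (no spatial mixing
  except through site gain), so scalp topographies are unrealistically
  diverse; microstate features on synthetic cohorts are correspondingly
  weak — consistent with the motivating study's finding that microstate
  features carried little predictive signal.
* EDF/BrainVision ingestion is not implemented here; recordings enter as
  in-memory matrices or plain-text exports. The preprocessing contract
  (`harmonize()` onward) is format-agnostic.
* The eLORETA module uses fixed scalar orientations; free-orientation
  (3-moment) sources and anatomical head models are out of scope.
* The noise-ceiling σ is a user input; the package makes no claim about
  any particular scale's test–retest reliability.
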