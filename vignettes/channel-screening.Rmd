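---
title: "Screening limited-channel EEG montages for physical and mental fatigue detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening limited-channel EEG montages for physical and mental fatigue detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegfatigue)
```

## The problem

Wearable EEG headbands expose only a handful of electrodes — here the four
10–20 positions TP9, AF7, AF8 and TP10, sampled at 256 Hz. For workplace
fatigue monitoring the practical question is not whether EEG carries fatigue
information (it does) but *which small subset of channels* carries enough of
it to detect both physically induced and mentally induced fatigue with a
single binary model, when the model must generalise to people it has never
seen.

`eegfatigue` implements that screening pipeline end to end:

1. **Segmentation.** Each subject-session recording follows a fixed protocol:
   a 3-minute baseline (s1), a 3-minute graded treadmill block (s2), a
   variable mental task-switching block (s3, up to 15 minutes), interleaved
   with three measurement probes (m1, m2, m3 of 2 minutes each). Signals are
   cut into non-overlapping 10-second windows of exactly 2560 samples; a
   3-minute event yields 18 windows, a 2-minute event 12.
2. **Features.** Sixteen features per window: four statistical moments
   (population denominators), seven entropies (sample, fuzzy, Shannon,
   Rényi, permutation, distribution, SVD) and five spectral quantities (band
   powers for delta 0.4–4, theta 4–8, alpha 8–12, beta 12–30 Hz, plus
   spectral entropy). Windows are averaged into one representative feature
   vector per (channel, event).
3. **Labelling.** Binary fatigue labels come from subjective scores:
   physical rows (s2) are labelled 1 when the score is ≥ the mean of all
   participants' high-intensity physical scores; mental rows (s3) against
   the mean of all mental-task scores; the rule is inclusive at the
   boundary. With pinned reference thresholds these are 45 and 36.
4. **Modelling.** Leave-one-subject-out (LOSO) cross-validation with SMOTE
   oversampling of the fatigued minority class applied inside each training
   fold only; exhaustive hyperparameter grids for regularised logistic
   regression, gradient boosting and an SVM; the base classifier is chosen
   by accuracy and F1 with recall as the tie-break.
5. **Screening.** All $2^4 - 1 = 15$ channel subsets are evaluated under the
   identical LOSO protocol with the frozen winning configuration and ranked
   by the cost-weighted Score
   $$\mathrm{Score} = \bigl(w\,r + (1-w)\,s\bigr) \times 100,\qquad
     r = \frac{TP}{TP+FN},\quad s = \frac{TN}{TN+FP},$$
   with $w = 0.8$: a missed fatigue case is treated as four times as costly
   as a false alarm. A feature-group ablation (statistical / entropy /
   frequency, their pairwise unions, and all features) and a per-task
   stratified confusion analysis complete the report.

## Parameters that matter

| Parameter | Default | Meaning / rationale |
|---|---|---|
| `m`, `r` | 2, 0.2 | Sample/fuzzy entropy embedding and tolerance (fraction of the window's population SD) — the common defaults of the driver-fatigue EEG literature. |
| `pe_order`, `pe_delay` | 3, 1 | Permutation entropy ordinal order/delay; PE ≤ log₂(3!) bits. |
| `renyi_alpha` | 2 | Rényi order (collision entropy); the α→1 limit recovers Shannon. |
| `histogram_bins` | 64 | Equal-width amplitude histogram over [min, max] for SnE/RE/DE. |
| `svd_embed_dim`, `svd_delay` | 10, 1 | Delay embedding for SVD entropy; SVDE ≤ log₂ 10 bits. |
| `welch_nperseg`, `welch_overlap` | 256, 0.5 | Welch PSD: 1-second Hann windows, 50 % overlap, mean removed per window → 1 Hz resolution within a 10-s epoch. |
| `w` | 0.8 | Recall weight of the Score; configurable per deployment risk appetite. |
| thresholds | derived (or 45 / 36) | Derived from cohort scores by default, pinnable to the reference values. |

## The synthetic cohort generator

Real recordings of this protocol are an external dataset; the generator
stands in for them so that every downstream stage is testable offline. Each
channel is a sum of four band-limited Gaussian oscillations (delta, theta,
alpha, beta, with per-subject weight jitter) over a pink-noise (1/f) plus
white background. Fatigue is injected as the feature families expect it:

* during s2, theta and alpha weights are multiplied by
  $1 + 0.6\,g_{\mathrm{phys}}\cdot I \cdot g_{ch}$ (intensity $I$ = 1/2/3
  for the low/medium/high session) and the signal is blended toward a
  5-sample moving average (entropy reduction), with blending weight
  $\min(0.9,\ 0.2\,g_{\mathrm{phys}} I g_{ch})$;
* during s3 likewise with the mental gain at unit intensity (the mental task
  protocol does not change across sessions);
* `channel_gains` (optionally a separate map for the mental task) localises
  the signature: it scales the *injected effect*, not the channel amplitude —
  a plain amplitude scale would survive feature standardisation and make all
  channels equally informative, defeating channel screening.

Subjective scores are $15 + 12\,I\,g_{\mathrm{phys}}$ (physical),
$15 + 25\,g_{\mathrm{mental}}$ (mental) and the baseline 15, each with
Gaussian noise of SD $3\times$ `noise_scale`, clamped at 0 — a 0–100 scale
whose high-intensity means sit near the reference thresholds. No particular
subjective instrument is implied; the 0-100 scale is a generator convention,
not a claim.

Per-subject heterogeneity is lognormal on the fatigue gains
(`gain_mean`, `gain_sd`) — subjects differ both in how fatigued they get
(scores → labels) and in how strongly their EEG shifts (features), which is
exactly the between-subject structure LOSO stresses.

**What the generator does not emulate:** eye-blink/EMG artifacts, electrode
pops, volume conduction, non-stationary drift, circadian effects, or any
realistic EEG microstructure. A green pipeline test therefore establishes
that the machinery is correct (no leakage, correct tallies, recoverable
injected effects), *not* that the method reaches any particular performance
on real recordings.

### What "strong effects" means here

Two acceptance properties run on synthetic cohorts: channel recovery (the
top-ranked subset contains the informative channels) and high LOSO recall of
the selected classifier under strong effects. Both need a *stated world*:

* **Strong effects = a susceptibility split, not a gain raise.** Labels
  derive from thresholds at the cohort score mean, so scaling every
  subject's gain up recentres the threshold and leaves the same borderline
  subjects borderline — uniform gain inflation cannot make the labels more
  learnable. The strong-effect reference world is therefore a two-level
  mixture: half the cohort responds strongly (gain 3.2), half weakly (0.8),
  with score noise at `noise_scale = 0.3`. Misclassifying a subject whose
  score sits on the threshold is a property of threshold labelling, not a
  pipeline defect, and the mixture removes that confound from the test.
* **Channel recovery needs channels that are individually insufficient.**
  If one channel carries both signatures, a single-channel model ties the
  pair at Score 100 and the fewer-channels tie-break correctly prefers it —
  the "recovery" test would then fail for the right behaviour. The recovery
  world therefore places the physical signature on TP9 and the mental
  signature on AF7: only subsets containing both can detect all fatigued
  rows.

### Scale reductions in the tests

A full default cohort (12 subjects × 3 sessions, 540-s mental task) is
roughly 18,000 windows of 2560 samples; the O(N²) sample/fuzzy entropy alone
makes that a multi-hour single-CPU computation. The test suite therefore
runs the *same* pipeline on reduced worlds: one or two sessions, a 60-s
mental block, and a cap on windows per event (`windows_per_event`), which
subsamples the windows entering the per-event average. Reductions change
statistical power, not semantics; every structural assertion (fold
disjointness, tally conservation, determinism, enumeration counts) is
scale-free.

## Numerical conventions

* Sample entropy uses the $N - m$ templates that support both comparison
  lengths, pairs $i<j$ only (no self-matches), Chebyshev distance, tolerance
  $r \times$ population SD. When either pair count is zero the value is
  capped at $-\log\frac{2}{(N-m-1)(N-m)}$, the largest observable value.
  Fuzzy entropy replaces the hard match with membership
  $e^{-(d/r_{tol})^2}$; a constant window gives 0 for both.
* Fuzzy membership terms with $(d/r_{tol})^2 \ge 45$ (below $3\cdot10^{-20}$)
  are skipped; the omission is beneath double rounding noise, and the
  compiled kernel's polynomial `exp` agrees with `libm` to ~1 ulp (the test
  suite checks equality with a naive R oracle at 1e-12).
* Ordinal patterns resolve ties by index order (stable ranks); SVD entropy
  uses eigenvalues of the embedding Gram matrix, clipped at zero, normalised
  to probabilities.
* Histogram entropies share one equal-width histogram over [min, max] with
  empty bins excluded; log bases follow the printed formulas: natural log
  for SnE/RE (and SE/FE/SpE), log₂ for PE/DE/SVDE.
* Band power integrates the Welch PSD over half-open bands
  $[f_{low}, f_{high})$ so shared edges are never double-counted. A raw DFT magnitude sum would
  also satisfy the band-power definition; Welch was chosen for estimator
  stability within a 10-s epoch and is the one place a re-implementation
  against other toolchains should expect small systematic differences.
* Event averaging happens at the *feature* level (after extraction), not on
  raw samples: averaging signals first would destroy the nonlinear features
  it feeds.
* Kurtosis is the raw fourth standardised moment (a Gaussian scores 3);
  zero-variance windows get Kur = SK = 0 with a logged flag (constant
  windows carry no shape information).
* Scores are ranked unrounded; *displayed* Scores round half-away-from-zero
  to integers. Ranking ties break by recall, then fewer channels (a
  practicality preference), then channel-label lexicographic order.
* Baseline (s1) rows are labelled against the minimum of the two thresholds:
  there is no established convention for baseline labelling, and with
  realistic baseline scores this rule yields the non-fatigued label; the rule is configurable
  (`label_policy(baseline_rule = ...)`).
* The grid-search objective is the Score of the confusion counts pooled over
  all LOSO folds (configurable to accuracy). Per-fold Scores are frequently
  undefined at nine rows per fold (folds without a positive or without a
  negative row), so pooling is used instead of a mean of per-fold Scores.
* Logistic regression is backed by `glmnet` with $\lambda = 1/(nC)$; the
  grid's `solver` axis is metadata under this backend (the invalid l1+lbfgs
  combinations are skipped, and candidates differing only in solver share
  one fit). The SVM (SMO) and gradient boosting are compiled
  implementations validated prediction-for-prediction against a reference
  implementation on a frozen fixture.
* Features are standardised with training-fold statistics before SMOTE and
  fitting (distance-based resampling and margin classifiers need comparable
  scales); whether the reference analysis standardised is unstated.
* One master seed is fanned out to every random consumer through a stable
  31-bit string hash (`derive_seed`), so runs are reproducible across
  platforms and any stage can be re-run in isolation.

## Known limitations

* The generator's fatigue signature is exactly the kind of shift the feature
  battery measures; it cannot falsify the *choice* of features, only their
  implementation and the protocol around them.
* With 3 rows per subject per session, LOSO metrics are high-variance;
  pooled confusion counts (not averaged per-fold metrics) are reported for
  that reason.
* The SVM uses working-set SMO with a 1e-3 duality-gap tolerance — adequate
  for these problem sizes, not a general-purpose SVM.
* No artifact handling or filtering is applied before segmentation (the
  protocol specifies none); a pass-through preprocessing hook exists for
  users who need one.
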