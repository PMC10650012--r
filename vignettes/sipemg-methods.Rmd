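---
title: "sipemg: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{sipemg: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the signal model behind the synthetic study generator, the preprocessing
and feature definitions, the evaluation protocol, and the reasoning behind
every numerical choice that the underlying protocol leaves open.

## 1. The analysis problem

Each swallow — of fluid, saliva or solid food — and each cough or spoken
word produces a transient burst of activity in the infrahyoid sEMG.
Given two-channel recordings (right/left sternohyoid, 2.2 kHz) of a cued
protocol in which a subject performs 60 drinking sips (12 each at 5, 10,
15, 20 and 25 mL) and 40 non-drinking events (10 each of talk, cough,
saliva swallow, solid swallow) per day, the pipeline answers two questions
per subject, day and channel:

* **Detection** — can drinking bursts be separated from all other events?
  Scored by the F-score (harmonic precision/recall mean) of the drinking
  class, appropriate for the imbalanced 60/40 design.
* **Estimation** — for drinking bursts, how much fluid was swallowed?
  Scored by RMSE in mL. With balanced volumes {5,...,25} mL the
  no-information floor (always predict the mean) is
  $\sqrt{\mathrm{mean}((v-\bar v)^2)} = \sqrt{50} \approx 7.07$ mL; the
  useful dynamic range of any estimator lies strictly between 0 and that
  floor.

## 2. The synthetic study generator

No public recordings exist for this protocol, so the generator is a
first-class module: it emulates the *statistical* structure that the
analysis depends on, not the physiology.

**Burst model.** Each event is band-limited Gaussian noise (2nd-order
Butterworth band-pass of white noise, unit RMS) multiplied by a smooth
unimodal Hann envelope, added to ever-present baseline Gaussian noise
(SD 0.05). This is the standard surrogate for interference-pattern sEMG:
it reproduces the qualitative burst morphology (an oscillatory, zero-mean
transient with a smooth amplitude profile) while remaining fully
parameterised and seedable.

**Class signatures.** The protocol gives no quantitative class model, so
the class parameters are free choices, fixed once, intended to make
classification hard but learnable (classes overlap in every single
parameter):

| class  | duration mean ± SD (s) | peak amplitude | carrier band (Hz) |
|--------|------------------------|----------------|-------------------|
| drink  | 1.0 ± 0.10             | 1.0            | 30–150            |
| saliva | 0.8 ± 0.10             | 0.85           | 30–150            |
| solid  | 1.2 ± 0.15             | 0.95           | 40–190            |
| cough  | 0.35 ± 0.05            | 2.2            | 20–350            |
| talk   | 1.8 ± 0.20             | 0.45           | 60–250            |

Talk is an intermittent train of 0.18-s sub-bursts (one per ~0.3 s,
amplitudes jittered), emulating syllabic activation; saliva is a shorter,
slightly weaker twin of drink, which is what makes detection non-trivial.

**Volume encoding.** For drinking bursts, peak amplitude is multiplied by
$(1 + 0.02\,v)$ and duration extended by $0.01\,v$ seconds ($v$ in mL),
with multiplicative log-normal per-sip noise (SD 0.10 on the log scale).
This calibration puts single-feature volume estimation in the regime the
protocol reports: feasible but clearly imperfect (ideal single-feature
RMSE sits roughly midway between 0 and the 7.07 mL floor). Setting both
slopes to zero gives the *null-effect mode* in which drinking bursts carry
no volume information and any honest estimator must approach the floor.

**Between-subject, between-day, between-channel structure.**
Multiplicative log-normal gains: per-subject (SD 0.15), per-subject-day
drift (SD 0.10), and a fixed right/left gain ratio of 1.15 (the protocol
reports systematically better right-side performance). Both sides of a
subject-day share one event schedule — they are two channels of one
session — but carry independent carrier noise. Events are laid out
sequentially at 4-s spacing with ±0.25 s jitter.

**Seeding.** All randomness derives from one root seed, split
deterministically per subject, day and side (multiplicative hash, children
kept below $2^{31}$), so a study is bit-reproducible and any single
recording can be regenerated in isolation.

**What the generator does not emulate** — and hence what passing tests do
*not* show about real data: motor-unit recruitment and firing statistics,
electrode-placement and skin-impedance effects, movement artefacts,
heart-beat contamination, non-stationarity within a session, and any
nonlinear volume dependence. Results on synthetic data validate the
*machinery* (segmentation accuracy, feature correctness, protocol logic),
not clinical performance.

## 3. Preprocessing

* **Band-pass**: Butterworth order 4, 10–400 Hz, applied forward-backward
  (`filtfilt`). Zero-phase filtering is essential here because the
  envelope peak defines the window centre; a causal filter would bias
  every peak time by its group delay.
* **Envelope**: rectification followed by a zero-phase Butterworth
  low-pass, default cutoff **1 Hz**. The envelope's only role in this
  pipeline is *peak localisation* (windows are cut from the band-passed,
  not rectified, signal). For locating a ~1-s burst, smoothing at the
  burst timescale acts as a matched smoother; a faster envelope (5–10 Hz)
  tracks burst morphology more closely, but on amplitude-modulated noise
  its argmax wanders on the flat top of the burst by ~100 ms, which would
  de-centre the windows. The test suite verifies that with the 1 Hz
  default ≥95% of drinking-burst peaks are found within 50 ms of the
  generator's true envelope peak.
* **Burst windows**: exactly `round(window_s * fs)` samples (4400 at the
  2-s default) centred on the envelope maximum found within ±1.5 s of the
  annotated event time. The local (rather than global) search is needed
  because the synthetic recordings are continuous, with 100 events per
  recording. Windows that would cross a recording edge are zero-padded
  and flagged; annotations outside the recording are skipped and reported,
  not fatal. Changing `window_s` changes the window length proportionally
  and nothing else, which is how the window-size sensitivity experiment
  (0.1–2 s) is run.

## 4. The 26-feature catalogue

All features are computed from the band-passed burst window; definitions
are in `?extract_features`. Settings that the underlying protocol leaves
unstated live in `spectral_config()` and are serialised with every run:

* **Amplitude thresholds** for ZC / WAMP / MYOP are multiples of the
  window RMS (0.05 / 0.5 / 0.5). Absolute thresholds would interact with
  the arbitrary amplitude units and the subject/day/side gains; RMS-scaled
  thresholds make these counts scale-invariant, which the test suite
  checks as a law (scaling a window by $c>0$ scales MAV, WL, DASDV, LOG
  by $c$ and leaves ZC, WAMP, MYOP, skewness, kurtosis, entropies
  unchanged).
* **Welch PSD**: Hann segments of 0.5 s with 50% overlap — 2 Hz
  resolution at 2.2 kHz, so spectral landmarks (MNF, MDF, PKF) of a pure
  tone are recovered to within one bin. Short-time features (SF, MFCC)
  use 256-sample frames with 50% overlap: they summarise time-frequency
  structure, where frame count matters more than per-frame resolution.
* **Model orders**: AR and LPCC order 4 (standard for short sEMG
  segments); MFCC with 20 mel filters and 12 coefficients (speech
  convention, Hamming frames).
* **Vector-valued features reduced to scalars**: the evaluation treats
  each catalogue entry as one number. AC is the first AR coefficient;
  MFCC and ECDF are means over their coefficients/evaluation points.
  LPCC is the mean of the first four cepstral coefficients — *not* the
  first alone, because the LPC-to-cepstrum recursion gives $c_1 = a_1$
  identically, so a "first LPCC" would duplicate AC exactly (and make
  quadratic discriminant fits singular whenever both are selected).
* **The two entropy features**: the catalogue distinguishes an
  amplitude-domain entropy (Shannon entropy of a 64-bin histogram of the
  window's amplitudes, `Entropy`) from the myopulse percentage rate
  (`MYOP`, fraction of samples above threshold); these are separate
  features with separate definitions.
* **Degenerate inputs**: a constant window has no spectrum; spectral
  features raise an error, and `extract_feature_matrix()` excludes such
  windows while recording the failure, so one bad event cannot poison a
  study. NaN samples are rejected outright.
* A structural note: with fixed-length windows AAC = WL/(N−1) exactly, so
  two catalogue features are proportional copies. This is inherited from
  the catalogue itself; discriminant-analysis collinearity warnings on
  such pairs during subset enumeration are expected and suppressed.

Every feature is verified, on 200 randomised windows, against an
independently coded direct-from-definition oracle (Toeplitz solve instead
of Levinson recursion for the AR fit, explicit histogram and periodogram
loops) at $10^{-9}$ relative tolerance; time-reversal and scaling laws are
checked exactly.

## 5. Evaluation protocol

* **Classification**: drinking = positive class vs. everything else.
  Stratified seeded 5-fold CV (stratification preserves the 60/40 ratio
  per fold; a flag disables it), features z-scored with training-fold
  statistics only, F-score of the drinking class averaged over folds.
  F is defined as 0 when the fold has no true or predicted positives.
* **Regression**: drinking events only (volumes exist only for sips),
  seeded 5-fold CV, RMSE in mL. Features standardised per training fold;
  for the ANN and SVR the target is also standardised and predictions
  back-transformed.
* **Models**: fixed documented defaults, no tuning — SVC/SVR radial with
  C = 1; random forest with 100 trees (seeded); deterministic 1-NN with
  smallest-index tie-break (a randomised tie-break would make integer
  -valued features such as ZC non-reproducible in low dimension); LDA/QDA;
  least squares; CART; lasso and ridge at fixed penalty 0.05 on
  standardised features (ridge in closed form; lasso by coordinate
  descent, verified against `glmnet`). The ANN is a feed-forward network
  with exactly two hidden layers of 36 and 16 tanh units and a linear
  output, trained full-batch by BFGS on half-MSE with L2 penalty $10^{-2}$
  (sized for ~50-sample training folds, where an unregularised network of
  this capacity memorises the fold), at most 2000 iterations, seeded
  initialisation; its analytic gradient is finite-difference-checked in
  the tests.
* **Subset search**: exhaustive over sizes 1–3 ($\binom{26}{1} +
  \binom{26}{2} + \binom{26}{3} = 26 + 325 + 2600 = 2951$ sets per model
  and cell). Size 4 is greedy by default — forward extension of the top
  50 size-3 sets per cell, plus extensions of the top across-subject mean
  sets so the global size-4 choice is evaluated in every cell — with
  exhaustive enumeration (14 950 sets) behind a flag. Ties break towards
  the lexicographically first feature-name set, making every argmax
  deterministic. Fold assignments depend only on (seed, labels, n), so
  all subsets and models are compared on identical splits, and per-fold
  standardised design matrices are precomputed once per cell.
  *Subject-specific* best = argmax per (subject, day, side, model, k);
  *global* best = argmax of the across-subject mean score, which the
  subject-specific best dominates by construction in every cell.
* **Cross-day transfer**: per subject and side, train on all of one day
  with that day's selected set, test on the other day, both directions
  reported plus their mean. Swapping the day arguments swaps the two
  directional scores exactly. Subjects present on one day only are
  excluded and reported.

## 6. Problem sizes and reproducibility

The package's own test and demonstration runs use reduced study sizes
chosen to exercise every code path at comfortable cost: property tests use
1–2 subjects (with the full 100-event subject-day wherever the 60/40
structure matters), the Monte-Carlo volume-trend check uses ≥200 bursts
per volume, the cross-day drift comparison aggregates 10 seeds, and the
acceptance script (`scripts/acceptance.R`) runs 3 subjects × 2 days × 2
sides with exhaustive search up to pairs. The drift comparison contrasts
zero drift against an elevated drift level (0.35) as the explicit
manipulation: at reduced scale, cross-day training on a full day slightly
*out-trains* the 80% CV folds, so the mild default drift (0.10) alone does
not measurably degrade transfer, while the causal effect of drift is
unambiguous at the elevated level.

Every stochastic step — generation, fold assignment, forest and network
seeds — derives from one root seed, and `run_pipeline()` writes a manifest
with MD5 checksums plus a canonical (key-order-invariant) hash of its full
configuration, so identical configurations provably produce identical
artifacts.

## 7. Known limitations

* The generator's class and volume models are linear and log-normal by
  construction; nothing guarantees real swallows behave this way.
  Conclusions transferable to real data are limited to the correctness of
  the machinery.
* The greedy size-4 search can miss the exhaustive optimum (the flag
  restores exhaustiveness at ~5× cost for size 4).
* Lasso/ridge use one fixed penalty rather than a tuned path, matching
  the no-tuning policy of the rest of the model zoo.
* QDA requires non-singular class covariances; on degenerate subsets
  (e.g. proportional feature pairs) its score is recorded as missing and
  the subset simply cannot win the search for that model.
* The 1 Hz envelope default is tuned to ~1-s bursts; much shorter bursts
  (e.g. rapid repetitive swallows) would need a faster envelope and a
  narrower peak-search half-width.
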