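---
title: "EMG-based assessment of hand motor recovery: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EMG-based assessment of hand motor recovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(emgrehab)
```

This vignette documents the science behind `emgrehab`: the assessment model
and its assumptions, every tunable parameter with its default and rationale,
what the synthetic cohort generator does and does not emulate, the numerical
conventions, and the design decisions taken where the methodology left
genuine choices open.

## The assessment model

The pipeline treats *movement classification accuracy* as a longitudinal
marker of hand motor recovery. A patient attempts 7 cued hand movements
(flexion, extension, opening, closing, pinch, pronation, supination) while
5 forearm muscles are recorded (extensor digitorum communis, flexor
digitorum superficialis, supinator, pronator teres, dorsal interossei) at
1926 Hz; each movement is performed as 3 repetitions of 5 s rest + 5 s
contraction. Early after stroke, antagonist co-contraction, reduced
selective activation and high variability make the movement-specific sEMG
patterns confusable, so a classifier trained per patient-week performs
poorly; as selective control returns, accuracy rises. Alongside, clinical
instruments (FMA-UE 0–66, ARAT 0–57, BBT) are administered at baseline and
weeks 4, 6 and 9, giving three analyses:

* **progression** — week-pair accuracy differences, averaged over the two
  arms, with paired t tests within arms and a between-arm one-way ANOVA on
  the per-patient difference scores (plus Shapiro-Wilk normality recorded);
* **association** — Spearman correlations between per-patient EMG feature
  summaries and clinical scores, labelled weak/moderate/strong at
  |ρ| = 0.3 / 0.6 (the labels are conventional; the cutoffs are
  configurable in `stats_config()` because published reports rarely state
  them numerically);
* **clinical effect** — the between-arm difference-in-differences of each
  instrument compared *strictly* against its MCID (9 / 6 / 6 points);
  a change equal to the threshold does not count as exceeding it.

## Preprocessing and windowing conventions

* Both filters are applied forward–backward (`signal::filtfilt`), i.e.
  zero-phase: contraction envelopes must not be delayed or smeared
  asymmetrically, and the methodology this replicates does not state phase
  handling, so the distortion-free choice is the default.
* The 50 Hz notch is realised as a 2nd-order Butterworth band-stop with
  Q = 30 (≈1.7 Hz bandwidth): narrow enough to spare the 20–450 Hz EMG
  band (a 100 Hz tone passes within 5%), wide enough to remove line
  interference by ≥ 20 dB.
* The bandpass is a 4th-order Butterworth, 20–450 Hz. "Order" here counts
  the overall filter order (`butter(2, ...)` on a band specification).
* Milliseconds convert to samples by *floor*: 250 ms at 1926 Hz is 481.5
  samples, and a deterministic convention is required; 481-sample windows
  advance by `floor(481 × 0.5)` = 240 samples, so a full 9630-sample
  contraction yields `floor((9630 − 481)/240) + 1 = 39` windows.
* Epoching is **cue-based**: contraction boundaries come from the
  acquisition sidecar (the protocol was visually cued with fixed timing),
  never from amplitude thresholds — onset detection would make the epochs
  depend on the very signal properties being measured. Each epoch is
  trimmed by a 250 ms guard at both ends to exclude the ramp transients;
  set `guard_ms = 0` for strict fixed-timing replication.

## The feature bank

Sixteen features per window and channel, concatenated across the 5 channels
(80 columns). The names are standard in myoelectric control but their exact
definitions vary across labs, so the conventions are pinned in
`feature_spec()` and tested against a naive direct-formula oracle:

* ZC and SSC use deadband thresholds defaulting to 0 (none was stated;
  clinical practice sometimes uses small positive deadbands, hence
  configurable).
* VAR and SD are sample statistics (N−1 denominator); RMS and average
  energy use N. The identities IEMG = N·MAV, AENG = RMS², VAR = SD² and
  WL = (N−1)·AAC hold to machine precision and are enforced by tests.
* CARD counts distinct values after sorting, merging sorted neighbours
  closer than `1e-4 ×` the window SD — tying the tolerance to the window
  scale makes the feature invariant under amplitude scaling.
* Kurtosis defaults to the Fisher (excess) convention; a constant window
  has undefined moments and is defined as 0 with a warning.
* MNF/MDF come from a Welch PSD (256-sample Hamming segments, 50% overlap)
  — lower variance than a raw periodogram on 481-sample windows; the
  periodogram mode exists for oracle tests. MDF interpolates linearly
  between frequency bins at half cumulative power.

## Classification choices

* **Cross-validation is grouped by repetition** (movement-stratified).
  Overlapping windows cut from one contraction share signal; splitting
  them across train and test would leak and inflate accuracy. A
  window-level mode exists for sensitivity analysis. With 3 repetitions
  per movement the natural default is 3 folds (one repetition per fold);
  `cv_spec()`'s generic default of 5 folds applies to richer protocols.
* **Models are per patient-week**, and accuracies are averaged within arm
  afterwards — the framing is each patient's movement performance, not a
  pooled recognizer.
* Hyperparameters are fixed (k = 5, 100 trees, RBF kernel with C = 1,
  features standardised on the training fold): tuning per patient-week
  would change the measurand being tracked longitudinally.
* Published accuracy summaries are scheme-dependent: the original trial
  did not state its validation protocol, aggregation level or
  hyperparameters, so absolute accuracy levels should only be compared
  within one scheme.

## The synthetic cohort generator

No patient-level data from such trials are deposited, so the generator
produces a cohort with the statistical structure the analysis assumes.
One latent per patient — class separability λ(w) = min(plateau,
λ₀ + gain·week) — drives everything:

* **Pattern distinctness.** Each patient has a fixed 7×5 activation-gain
  matrix `A` (drawn once, reused at every week). At week w the effective
  pattern is `(1−λ)·Ā + λ·A[m,·]`, with Ā the movement-averaged
  (confusable) pattern: at λ = 0 all movements look alike, at λ = 1 they
  are fully distinct.
* **Jitter.** Per-repetition, per-channel multiplicative log-normal jitter
  with scale `jitter0 · jitter_decay^λ` models unstable selective
  activation that settles as recovery proceeds.
* **Amplitude.** Overall gain `1 + amp_gain·λ` — recovery increases sEMG
  amplitude, which is what makes amplitude-family features correlate with
  clinical scores cross-sectionally. Each patient's activation matrix is
  normalised to a common grand mean so that between-patient amplitude
  differences reflect recovery rather than electrode/anatomy nuisance.
* **Carrier and noise.** The sEMG carrier is amplitude-modulated,
  bandlimited (20–450 Hz) Gaussian noise — the standard interference-
  pattern surrogate; motor-unit simulation is out of scope. The envelope
  is a trapezoid with 250 ms ramps, exactly zero during rest. On top:
  white noise at `snr_db` (8 dB default, relative to mean clean
  contraction power), 50 Hz line interference (`line_amp` = 0.05 mV) and
  sub-2 Hz drift (`drift_amp` = 0.2 mV) — the two artifacts the notch and
  bandpass exist to remove.
* **Clinical link.** Scores follow
  `score = clamp(round(B + β·λ_c(w)·range + ε))` with
  `λ_c(w) = λ₀ + clinical_gain·(λ(w) − λ₀)`. Anchoring the arm-specific
  `clinical_gain` on *progress from baseline* keeps the arms balanced at
  baseline (as randomisation would) while letting the clinical contrast
  between arms exceed the EMG contrast — trials of this design report
  a large clinical gap with a modest accuracy gap, which a single shared
  latent cannot produce without this extra degree of freedom.
* **Heterogeneity.** Patients draw individual λ₀ (SD 0.04) and
  multiplicative gain variation (SD 0.3 on the log scale). This is what
  makes week-9 cross-sectional EMG–clinical correlations recoverable: at
  a fixed week, patients differ in how far they have recovered.
* **Seeding.** One master seed; every (patient, week, movement) recording
  derives its RNG stream by a 31-bit FNV-style hash, so any subset of the
  dataset regenerates bit-identically.

### Calibration of the defaults

The defaults were set in one design pass and then frozen. λ₀ = 0.4 with
experimental gain 0.042/week (plateau 0.92) and control gain 0.028/week
puts mean three-classifier accuracy near 35% at baseline and in the high
70s–80s at follow-up — the vicinity reported for this design — with the
experimental arm ahead at weeks 6 and 9. The clinical slopes
(β = 1.1 / 1.2 / 1.7 with BBT scale 45, score noise SD 1.5) give pooled
Spearman ρ(λ, score) ≥ 0.7 for each instrument and difference-in-
differences above the MCIDs (≈11–12 FMA-UE points against the 9-point
threshold) when the arms use the default rates; with identical rates the
contrast vanishes. No claim is made that simulated trajectories reproduce
any real cohort.

### What passing tests do and do not show

The generator emulates: the acquisition protocol and channel count, line
and drift artifacts, rest/contraction structure, low baseline separability
with arm-specific recovery, and a monotone clinical link. It does **not**
emulate motor-unit physiology, spasticity, fatigue within a session,
electrode shift between sessions, or missing visits. Tests passing on this
cohort validate the pipeline's *machinery* (filters, features, leakage-safe
evaluation, statistics) and its ability to recover a known generative
contrast — they do not validate clinical claims about real patients.

## Problem sizes used in tests and drivers

Simulation-heavy tests and the analysis drivers run on a shortened
protocol (1 s rest / 2 s contraction × 3 repetitions; 11 windows per
trimmed epoch instead of 35) and cohorts of 3–10 patients per arm — the
windowing, feature and classifier code paths are identical to the
full-length protocol, which the duration, windowing-arithmetic and
noiseless-separability tests exercise directly. The acceptance script uses
4 patients per arm for the accuracy contrast, 10 for the correlation, and
the full 26 per arm for the clinical analysis (which needs no signal
simulation). These sizes are the package's own choices for a desk-scale
demonstration; nothing prevents running the full protocol end-to-end.

## Known limitations

* Absolute classification accuracies are scheme-dependent (validation
  design, aggregation, hyperparameters) and should not be compared across
  schemes.
* The EMG summary entering each correlation is the grand mean over
  windows, repetitions, movements and channels — the least-assuming
  reading; per-channel and median modes exist, and conclusions may be
  sensitive to this choice.
* Raw p-values are reported by default (replication mode); a
  Benjamini-Hochberg mode is available in `stats_config()` and should be
  preferred for confirmatory use.
* The generator's single-latent design makes EMG and clinical trajectories
  intrinsically coupled; it cannot model dissociations (e.g. improved
  dexterity without EMG change).
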