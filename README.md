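# emgrehab

Longitudinal, EMG-based assessment of hand motor recovery after stroke.

Clinical trials of hand rehabilitation usually track recovery with
therapist-administered scales — the Fugl-Meyer Assessment of the upper
extremity (FMA-UE, 0–66), the Action Research Arm Test (ARAT, 0–57) and the
Box and Block Test (BBT, blocks/min). Surface electromyography (sEMG) of the
forearm offers an objective complement: as selective muscle activation
returns, movement-specific sEMG patterns become more distinct, and a
classifier trained to recognise attempted movements from sEMG features gets
more accurate. `emgrehab` implements that assessment methodology as a tested
R pipeline for a two-arm longitudinal design (assessments at baseline and
weeks 4, 6 and 9):

1. **Preprocessing** — 50 Hz zero-phase notch (Q = 30), fourth-order
   Butterworth 20–450 Hz bandpass, cue-based contraction epoching, and
   overlap windowing (250 ms windows, 50% overlap; at 1926 Hz that is
   481-sample windows advancing by 240).
2. **Feature bank** — 14 time-domain features per window and channel (RMS,
   MAV, IEMG, SSC, ZC, PTP, VAR, SD, WL, CARD, IQR, kurtosis, average
   energy, AAC) plus mean and median frequency from a Welch power spectrum;
   with 5 channels that is an 80-column feature table per window.
3. **Movement classification** — per patient and week, KNN / random forest /
   RBF-SVM classify the 7 movements (flexion, extension, opening, closing,
   pinch, pronation, supination) under repetition-grouped, movement-
   stratified cross-validation; accuracies feed longitudinal progression
   statistics (paired t within arms, ANOVA between arms) and
   across-classifier mean summaries.
4. **Clinical statistics** — Spearman correlations between per-patient EMG
   feature summaries and clinical scores with weak/moderate/strong labels
   (|ρ| cut at 0.3 / 0.6), Mann-Whitney group comparisons, Shapiro-Wilk
   normality checks, and the MCID analysis: the between-group
   difference-in-differences
   `DiD = (exp_post − exp_pre) − (ctrl_post − ctrl_pre)`
   is compared (strictly) against the minimal clinically important
   differences 9 (FMA-UE), 6 (ARAT) and 6 (BBT).
5. **Synthetic cohort generator** — patient-level sEMG and clinical scores
   are not publicly available for such trials, so the package ships a
   generative surrogate: each patient carries a latent class-separability
   λ(w) = min(plateau, λ₀ + gain·week) that drives (a) how distinct the
   7×5 muscle-activation patterns are, (b) within-class jitter, (c) overall
   amplitude, and (d) clinical score improvement. Both study arms share the
   acquisition protocol (5 s rest / 5 s contraction × 3 repetitions per
   movement, 5 forearm channels at 1926 Hz) but differ in recovery rates,
   so classifier accuracy, EMG–clinical correlations and MCID effects are
   all recoverable from one latent process.

## Worked example

Published group-level summaries of a two-arm trial (26 patients per arm)
ship under `inst/extdata/trial_summary/`. The MCID worked example:

```r
library(emgrehab)
ts <- function(f) system.file("extdata", "trial_summary", f, package = "emgrehab")
m <- read.csv(ts("clinical_means.csv"))
pub <- do.call(rbind, lapply(split(m, m$instrument), function(d)
  data.frame(instrument = d$instrument[1],
             diff_in_diff = diff_in_diff(
               d$experimental_mean[d$timepoint == "pre"],
               d$experimental_mean[d$timepoint == "post"],
               d$control_mean[d$timepoint == "pre"],
               d$control_mean[d$timepoint == "post"]))))
print(pub, row.names = FALSE)
#>  instrument diff_in_diff
#>        arat         8.96
#>         bbt        20.46
#>      fma_ue         9.46
```

All three exceed their MCIDs (6, 6, 9): the experimental arm's extra
improvement is clinically meaningful on every instrument. Averaging the
published per-classifier accuracies with `classifier_mean_summary()` gives
the across-classifier means (e.g. experimental follow-up
mean(84.68, 83.52, 82.56) = 83.59%), and `progression_table()` reproduces
the week-pair progression cells (KNN baseline→week 4: 15.93 points;
follow-up−baseline: 42.14 points).

The full synthetic workflow lives in `analysis/01_simulate.R` …
`analysis/04_clinical.R` (run them from the repository root in order; an
8-patients-per-arm demo cohort, ~3 minutes total). Driver 04 printed, for
the demo seed:

```
week-9 RMS vs FMA-UE:
          group  rho       p strength significant
73      control 0.50 0.21617 moderate       FALSE
91 experimental 0.96 0.00018   strong        TRUE

simulated-cohort outcome analysis:
  instrument diff_in_diff mcid exceeds_mcid
1     fma_ue        11.12    9         TRUE
2       arat         9.38    6         TRUE
3        bbt        21.88    6         TRUE
```

— the faster-recovering arm shows strong, significant week-9 EMG–clinical
correlations and a clinically meaningful between-group effect, exactly the
structure the generator encodes.

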