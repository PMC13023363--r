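# taperstates

Seizure-state decomposition and anti-seizure medication (ASM) taper analysis
for intracranial EEG (iEEG).

When ASMs are withdrawn during pre-surgical iEEG monitoring, seizures become
more frequent and longer. Two drug mechanisms can produce the lengthening:
dose-dependent prolongation of the seizure activity patterns that were
already there, and all-or-nothing reappearance of activity patterns the drug
had been suppressing. `taperstates` is for researchers analysing iEEG cohorts
who want to separate these mechanisms. It provides:

* **Preprocessing** — anti-aliased resampling to 512 Hz, zero-phase 4th-order
  Butterworth band-pass (0.5–200 Hz) with 2 Hz notches at 50 Hz and
  harmonics, iterative robust noisy-channel screening, common-average
  re-referencing, and the seizure inclusion rules (120 s lead-seizure rule,
  flagged-period exclusions).
* **Seizure states** — per-region band power (δ/θ/α/β/low-γ/high-γ) in 5 s
  windows with 1 s hop, z-scored to the pre-ictal baseline, assembled into a
  non-negative matrix `X` and factorized by NMF, `X ≈ W·H`: columns of `W`
  are spatio-frequency patterns ("states"), rows of `H` their per-window
  expression. Windows are hard-assigned to the strongest state or to a null
  state below an expression threshold.
* **ASM levels** — dosing schedules to plasma concentration via
  one-compartment first-order kinetics `C(t) = Σᵢ Sᵢ·ka/(ka−ke)·(e^{−ke·Δtᵢ}
  − e^{−ka·Δtᵢ})`, 6 h moving-average smoothing, normalization
  `BPCnorm = (BPC − mean(BPC_steady)) / (range(BPC_typical)/2)` so the
  pre-taper level fluctuates within ±1, multi-drug combination, and condition
  labels (typical `[−1, 1]`, tapered `< −1`, excluded `> 1`).
* **Taper-emergent states (TES)** — states occurring only in
  tapered-condition seizures, per-seizure TES duration proportions and
  first-appearance ordinals, and a within-subject permutation null for the
  TES duration effect.
* **Statistics** — the duration mixed model
  `log10(dur) ~ ASM level + sin/cos(24 h) + sin/cos(12 h) + (1 | subject)`,
  LMM-corrected durations (residual + level effect), the category model with
  TES-containing seizures as reference, Wilcoxon signed-rank and rank-sum
  tests with effect size `r = |z|/√N`, and labelled log10-to-percent
  conversions.
* **A synthetic-cohort generator** with full ground truth (planted patterns,
  state sequences, gated TES, duration model, condition-locked seizure
  rates), used by the test suite for end-to-end parameter recovery.

## Worked example

```r
library(taperstates)

cfg <- synthetic_config(n_subjects = 6, n_states_per_subject = 3,
                        n_taper_emergent = 1, regions_per_subject = 6,
                        rate_typical = 1, rate_tapered = 2.5,
                        n_days = 7, noise_sd = 0.15, seed = 5)
res <- run_pipeline(cfg, "run1", nc = 3)
writeLines(readLines(file.path("run1", "report.txt")))
```

```
Seizure-state / ASM taper analysis report
subjects: 6, retained seizures: 55
frequency, tapered vs typical (paired signed-rank): r = 0.64, p = 0.116
duration ~ ASM level mixed model: beta1 = -0.0797 (p = 8.03e-07); ~20% longer per unit withdrawal
category model (ref = TES-containing): beta_tapered = -0.192, beta_typical = -0.369
```

Reading the numbers: most of the six synthetic subjects seized more often per
day under tapering (paired signed-rank r = 0.64; at n = 6 the test has little
power, hence p = 0.12). The fitted duration slope −0.0797 log10 s per
normalized ASM unit is steeper than the planted −0.033 because this demo
cohort also plants taper-emergent states whose two-fold duration bonus
concentrates at low ASM levels — the model attributes part of that gating
effect to the slope, which is exactly why the category model is fitted next:
with TES-containing seizures as reference, tapered (−0.192) and typical
(−0.369) seizures without TES are substantially shorter, recovering the
planted ~0.3 log10 (two-fold) bonus. All tables behind these lines (seizure
table with per-seizure ASM levels and categories, state sequences, state
classes, dosing) are written to the run directory as CSV/JSON.

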