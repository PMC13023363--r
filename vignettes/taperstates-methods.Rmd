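---
title: "Methods: seizure states, ASM levels, and taper analysis"
author: "taperstates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seizure states, ASM levels, and taper analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taperstates)
```

## The problem

During pre-surgical intracranial EEG (iEEG) monitoring, anti-seizure
medication (ASM) is often withdrawn to provoke seizures. Two distinct drug
mechanisms can explain why seizures lengthen as drug levels fall: existing
seizure activity patterns may simply run longer (a graded, dose-dependent
effect), or activity patterns that the drug suppressed outright may reappear
(an all-or-nothing gating effect). `taperstates` implements an analysis that
separates the two: it decomposes each subject's seizures into recurring
spatio-frequency *states*, estimates a continuous normalized ASM exposure
from the dosing schedule, identifies *taper-emergent states* (TES) — states
confined to seizures in the tapered-drug condition — and quantifies dose
effects on seizure frequency and duration with mixed-effects and rank
statistics. A synthetic-cohort generator with known ground truth provides a
parameter-recovery test surface for every stage.

## iEEG preprocessing

Seizure clips (channels × samples, with a 120 s pre-ictal lead-in) are:

1. **Resampled to 512 Hz** when acquired faster, by zero-phase Butterworth
   anti-alias filtering (cut-off 0.45 × target rate) followed by exact
   decimation for integer rate ratios, or spline interpolation at the new
   sample times otherwise. Upsampling is refused. We deliberately avoid
   polyphase resamplers that leave an uncompensated group delay; the
   filter-then-interpolate route is delay-free by construction and is checked
   against an analytically sampled sinusoid.
2. **Filtered** with a zero-phase (forward–backward) 4th-order Butterworth
   band-pass, 0.5–200 Hz, implemented as a high-pass/low-pass cascade (two
   poles per edge). The cascade is numerically better conditioned than a
   single band-pass polynomial whose lower edge sits at 0.5 Hz; channels are
   demeaned first, since the slow 0.5 Hz pole otherwise leaves a tiny
   numerical DC residue. Mains interference is removed with 4th-order
   band-stop notches of total width 2 Hz (f ± 1 Hz) at 50 Hz and harmonics up
   to 200 Hz.
3. **Screened for noisy channels** per subject: each channel's log variance
   over the pre-ictal segments of all that subject's seizures is
   robust-z-scored (median and scaled MAD) across channels; channels with
   |z| > 3 are flagged and the rule is iterated on the retained set to a
   fixed point, then unioned with a user-supplied manual list. We use
   median/MAD rather than mean/SD because a single extreme channel inflates
   the SD enough to mask itself (with six channels the largest attainable
   classical |z| is about 2). This automatic screen is a deterministic
   stand-in for screening-plus-visual-validation workflows and is labelled as
   such in reports. Exclusions apply subject-wide.
4. **Re-referenced to the common average** of retained channels.
5. **Reduced to lead seizures**: within each subject, a seizure is dropped
   when its onset follows the previous *retained* seizure's offset by less
   than 120 s (measuring against the most recent retained seizure makes a
   whole cluster collapse onto its lead). Seizures flagged after sleep
   deprivation, cortical stimulation, or inside excluded drug periods are
   dropped with logged reasons.

## Seizure states

For each seizure, band power is computed in 5 s windows advanced by 1 s (4 s
overlap), anchored at clinical onset with the last partial window dropped, by
integrating a one-segment rectangular-window periodogram over six bands
(δ 1–4, θ 4–8, α 8–13, β 13–30, low-γ 30–60, high-γ 60–100 Hz). Powers are
log10-transformed, averaged over the channels of each brain region, and each
(region, band) series is z-scored against the same quantity computed on the
pre-ictal windows (≥ 30 s of baseline required; a zero baseline SD is an
error naming the offending pair).

All of a subject's seizures are assembled into a non-negative matrix **X**
with one row per (region, band) — region-major, band-minor — and one column
per window, concatenated across seizures. Negative z-scores are clipped at
zero by default: states are defined by power *increases* over the pre-ictal
baseline, and clipping preserves that semantics. (A shift-by-minimum
alternative is available but off by default, since it lets large baseline
deficits masquerade as activity.)

**X** is factorized as X ≈ W·H by non-negative matrix factorization with
multiplicative updates from a deterministic non-negative double-SVD
("NNDSVD-a") initialization; zero initial entries are filled with a small
multiple of the matrix mean to avoid locked zeros. Iteration stops when the
relative Frobenius error improves by less than 1e-7 per ten iterations, the
fit is exact to machine precision, or 10 000 iterations elapse. Columns of W
(spatio-frequency patterns) are rescaled to unit maximum with compensating
row scaling of H, so expression values are comparable across states. With a
fixed seed the fit is bit-reproducible.

Each window is hard-assigned to its most strongly expressed state (argmax
over the H column); ties go to the lowest component index, and windows whose
maximum expression falls below a threshold get a *null* state. The default
threshold is the 25th percentile of per-window expression maxima across the
subject's data — a subject-relative, scale-free rule; an absolute override is
available and recorded in output metadata.

The number of states is chosen per subject as the smallest candidate whose
split-half stability (seizures split into halves, NMF fitted to each, W
columns matched one-to-one by cosine similarity, matched cosines averaged) is
at least 0.8 *and* whose error curve has flattened (the next component
improves the relative error by under 5%, or the fit is already essentially
exact). State matching uses exhaustive permutation search, which is cheap for
the small state counts involved (≤ 7). An explicit override is logged.

## ASM levels

Dosing schedules (drug, dose, intake time) are converted to blood plasma
concentration (BPC) with a standard one-compartment model with first-order
absorption and elimination: a dose S taken at t₀ contributes
S·ka/(ka−ke)·(e^{−ke·Δt} − e^{−ka·Δt}) for Δt ≥ 0, and doses superpose
(linear kinetics). Per-drug ka and ke defaults, bundled as an editable JSON
file, derive from published half-lives and times-to-peak of common ASMs; the
dose-to-concentration scale is arbitrary because normalization removes it.
Exact intake clock times are usually unknown, so scheduled slots map to fixed
default clock times and the series is smoothed with a 6 h moving average
advanced hourly (5 h overlap), window means stamped at window centers.

Each drug's smoothed series is normalized by centring on its mean over the
*steady interval* (recording start until the first taper event) and dividing
by half its range over that interval, so the pre-taper level fluctuates
within about ±1. Multiple drugs are combined by averaging the *normalized*
series and re-normalizing with the same interval — averaging normalized
rather than raw concentrations keeps drugs with very different absolute
concentrations on an equal footing (this choice is flagged in output
metadata). Two properties pin the construction and are property-tested over
randomized schedules: after normalization the typical-period range is exactly
2 and the steady-period mean exactly 0.

Levels in [−1, 1] are the **typical** condition, below −1 **tapered**, above
+1 **excluded** (rescue medication). Each seizure takes the level at its
onset (linear interpolation): onset level is the exposure; duration is the
outcome.

## Taper-emergent states

Subjects qualify for TES analysis with at least three retained seizures and
at least one in each condition; others are skipped with a reason. A state
*occurs* in a seizure when it is assigned at least one window there (a
configurable minimum guards against single-window flicker). A state is
**taper-emergent** when every seizure it occurs in is in the tapered
condition; all other observed states are **dose-independent**. Seizures are
categorized as TES-containing (necessarily tapered), tapered-without-TES, or
typical. For TES-containing seizures we report the fraction of non-null
windows occupied by TES states — non-null windows, because the quantity
describes the share of seizure *activity*, not of elapsed time — and the
ordinal position of the first TES state in the run-length-encoded sequence.

**Permutation null.** To ask whether the extra duration of TES-containing
seizures exceeds chance, condition labels are shuffled within subject
(preserving each subject's condition counts), pseudo-TES states are re-derived
from the shuffled labels, seizures are re-categorized, and the rank-sum z of
log-durations (TES-containing vs the rest) is recomputed; p is the fraction
of permuted effects at least as large as the observed one. Two properties of
this scheme deserve note. First, permutations in which no pseudo-TES arises
carry no effect and are excluded rather than scored as zero; scoring them as
zero would make the test anti-conservative. Second, the shuffle can leave the
*true* TES set intact when typical labels are few — each genuine TES state
survives with probability roughly (1 − f_typ)^m, with f_typ the typical
fraction and m its carrier count — which contaminates the null towards the
observed effect and makes the test conservative. Calibration simulations
(no planted bonus) confirm conservative, never anti-conservative, p-values;
power simulations therefore use a balanced design (taper beginning
mid-recording, comparable rates in both conditions, a well-carried TES
state), where a planted +0.3 log10 bonus is detected at p < 0.05 in ≥ 90% of
seeds. This within-subject shuffle is a desk-scale analogue of nulls built
from non-tapered control subjects, not a replication of them.

## Duration statistics

Durations are analysed as log10 seconds (raw durations are heavy-tailed).
The central model is a REML linear mixed-effects regression

log₁₀(duration) ~ level + sin(2πT/24) + cos(2πT/24) + sin(2πT/12) + cos(2πT/12) + (1 | subject)

with T the onset clock time; the circadian pairs prevent 24 h/12 h duration
rhythms from masquerading as drug effects, and the subject random intercept
absorbs systematic between-subject duration differences. Fixed-effect
p-values use the Satterthwaite approximation. Singular fits (zero
between-subject variance) warn and report the boundary fit. *Corrected
durations* are residuals with the level effect added back — subject offsets
and circadian terms removed, exposure effect retained; the identity
corrected − residual = β₁·level holds exactly and is tested.

Categories are compared with log₁₀(duration) ~ category + (1 | subject),
treatment-coded with TES-containing seizures as the reference, restricted to
subjects that have TES.

Rank statistics report the effect size r = |z|/√N: the paired signed-rank z
(tie-corrected normal approximation, continuity correction off by default —
this convention reproduces the canonical r = 0.87 for 28 uniformly positive
paired differences, and both settings round to the same two decimals) for
frequency contrasts, and the tie-corrected rank-sum z for group contrasts.
Both are cross-checked against `stats::wilcox.test` in the test suite.

A log10 coefficient β converts to percentages under three labelled
conventions, because both directions appear in practice: percent *remaining*
(100·10^β), percent *increase per unit decrease* (100·(10^{−β}−1)), and
percent *decrease* (100·(1−10^β)). For example β = −0.2 leaves 63% of the
duration; β = −0.033 means ≈ 8% longer per unit of withdrawal; β = −0.058
means a 12.5% decrease per unit. The functions never silently unify these.

Per-subject seizure frequency is the count of retained seizures in a
condition divided by the days spent in it; a condition never observed yields
a missing value (not zero), which paired tests then exclude.

## The synthetic cohort generator

The generator is first-class, tested code: it draws cohorts in the pipeline's
own input formats with a ground-truth sidecar, so every stage has a
recovery test. Defaults describe the study conditions the package targets:
28 subjects observed ~10 days, twice-daily dosing with a linear taper from
day 3, five planted states per subject on disjoint region blocks (two of
them taper-emergent, gated to ASM levels below −1), per-subject duration
offsets N(1.85, 0.3) log10 s, slope −0.033 log10 s per normalized unit,
subtle circadian amplitudes (0.05 and 0.03 log10 s), residual SD 0.2, rates
0.5/day (typical) vs 2.5/day (tapered), and a +0.3 log10 duration bonus for
TES-containing seizures. A below-gate seizure carries a TES state with
probability 0.4, matching the sparse TES occurrence observed in real cohorts
(roughly 4 of 11 seizures in subjects that have such states).

Design choices worth recording:

* **Condition-locked rates.** Onsets come from Poisson thinning against the
  *interpolated* ASM level — the tapered rate applies exactly where the
  analysis will label "tapered". Switching rates at the nominal taper start
  instead would mislabel the lag period (plasma kinetics trail the schedule)
  and distort frequency contrasts.
* **Lead-seizure pairs are generated, not pre-filtered**, so the 120 s
  inclusion rule is exercised downstream; candidate onsets that would overlap
  an ongoing seizure are discarded. The ground-truth "retained" table applies
  the same rule the pipeline will apply.
* **Durations and TES flags are fixed before retention filtering**, and
  coverage enforcement (every dose-independent state anchored in a typical
  seizure, every TES state carried by an existing TES-carrying seizure) only
  edits state sets in ways that preserve each seizure's TES flag — durations
  are never retrofitted.
* **Feature tier** emits the z-score arrays directly (active pattern column
  × expression gain 3 + Gaussian noise); the **signal tier** synthesizes raw
  multichannel traces as unit-SD baseline noise plus band-limited Gaussian
  noise shaped by the active pattern column, so window band power is monotone
  in the planted pattern. No spike morphology is attempted: band power is the
  only feature the pipeline consumes.

What passing tests on this generator do *not* show: robustness to real ictal
waveform morphology, electrode artifacts beyond amplitude outliers, sleep and
multidien structure, rescue-medication boluses (beyond an excluded-period
flag), measured serum levels, or nonlinear/saturable pharmacokinetics. These
are out of scope by design.

## Numerical and testing notes

* State-recovery accuracy is scored with the expression threshold disabled:
  planted sequences contain no sub-threshold windows, and the default
  25th-percentile rule nulls a quarter of windows by construction, which
  would cap accuracy at 75% independent of recovery quality. The threshold
  rule is tested on its own worked examples instead.
* Slope-recovery simulations plant no TES states: the duration model carries
  no TES term, and a TES bonus co-varying with low levels would bias the
  slope; the simulation isolates the continuous mechanism.
* Simulation sizes: single-subject cohorts across 20 seeds for NMF state
  recovery (noiseless and 0.5 z-units of noise), 100 replicates for slope
  bias/coverage and 200 for the type-I rate at the 28-subject scale, 100
  randomized schedules for the normalization pinning property, and 120–199
  permutations per null. These sizes keep the full suite around ten minutes
  on one CPU while leaving Monte-Carlo error well inside the asserted
  margins.
* Reproducibility: every stochastic step flows from one seed; pipeline runs
  write a manifest (config echo, seed, package version) and re-running a
  completed directory is a no-op without `force`.

## Worked example

```{r example, eval = FALSE}
cfg <- synthetic_config(n_subjects = 6, n_states_per_subject = 3,
                        n_taper_emergent = 1, regions_per_subject = 6,
                        rate_typical = 1, n_days = 7, seed = 5)
res <- run_pipeline(cfg, "run1", nc = 3)
readLines(file.path("run1", "report.txt"))
```

The report states the paired frequency effect (r, p), the fitted duration
slope with its per-unit percentage, the category contrasts against
TES-containing seizures, and (when enabled) the permutation p for the TES
duration effect — the same sequence of results the analysis is designed to
reproduce on real cohorts.
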