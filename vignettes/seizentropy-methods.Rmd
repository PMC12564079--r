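---
title: "Methods: entropy-based PNES/ES discrimination and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: entropy-based PNES/ES discrimination and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Psychogenic non-epileptic seizures (PNES) mimic epileptic seizures (ES)
clinically but have no electrophysiological ictal signature, so
differential diagnosis from routine EEG is hard and misdiagnosis common.
The working hypothesis of this pipeline is that the two conditions differ
in how EEG *irregularity* evolves between brain states: PNES shows a drop
in signal complexity from the interictal baseline to the preictal period,
while ES shows no consistent within-subject change. The pipeline therefore
analyses three conditions per subject — interictal, preictal, and a
**dynamic** condition defined element-wise as preictal minus interictal
entropy per 5-s epoch and channel. With this sign convention a preictal
complexity loss is negative, which is what the PNES generative model in
the cohort simulator produces.

Each one-minute, 17-channel recording yields a 12 x 17 entropy matrix per
state (twelve 5-s epochs of 640 samples at 128 Hz); stacking subjects
gives the design matrix for statistics and classification (888 x 17 for a
46 + 28 cohort). Inference is strictly subject-level: statistics compare
per-subject summaries, and classification aggregates the 12 epoch
predictions of a held-out subject into one label by majority vote.

## Entropy estimators and their parameters

Nine estimators cover template, symbolic, phase, spectral and
time-frequency notions of irregularity. All logarithms are natural;
normalised measures (PermEn, DispEn, PhasEn, SpecEn, WaveEn) divide by the
log of their pattern-space size and live in [0, 1]; SampEn, FuzzyEn,
CondEn and RenEn are reported in nats.

| measure | parameters (defaults) | notes |
|---|---|---|
| SampEn | m, r (2, 0.2) | r is a fraction of the *epoch's* SD, converted per epoch per channel; Chebyshev distance, self-matches excluded; zero matches at either length yields `NA`, never a fabricated number; zero-variance epochs give 0 |
| FuzzyEn | m, r, n (2, 0.2, 2) | baseline-centred templates, membership `exp(-(d/r)^n)`; finite whenever the signal varies |
| PermEn | m (3), tau = 1 | ordinal patterns, ties broken by order of occurrence |
| DispEn | m, c (2, 6) | normal-CDF mapping of the standardised epoch, uniform quantisation into c classes |
| CondEn | m, c (2, 6) | `H(m) - H(m-1)` with the (m-1)-marginal taken over the same window positions, so it equals the conditional next-symbol entropy exactly and is bounded by `ln c` |
| PhasEn | k (8) | analytic-signal (Hilbert) phase histogram over k equal sectors of (-pi, pi] |
| SpecEn | — | one-sided FFT power spectrum, DC excluded |
| RenEn | alpha (2) | Renyi entropy of the *same spectral distribution* as SpecEn; the amplitude-histogram variant is deliberately not offered, keeping the measure in the spectral lineage it comes from in the EEG literature |
| WaveEn | 16 log-spaced Morlet scales over 0.5–40 Hz, centre-frequency parameter 6 | relative scalogram energies per scale |

Per-state defaults follow the tuned selections used for all headline
analyses: e.g. SampEn (1, 0.2) preictal but (2, 0.1) dynamic, PermEn m = 3
preictal but m = 5 elsewhere, PhasEn k = 16 for preictal/dynamic and k = 8
interictal. Note the PhasEn defaults sit outside the k in {4, 8, 12}
tuning grid; both the grid and the defaults are supported and
`default_entropy_params()` documents the choice. For the dynamic condition
the same parameters are applied to both states so the contrast reflects
state change, not configuration change.

The two O(N^2) pair-counting kernels (SampEn, FuzzyEn) are implemented in
C++ (Rcpp); everything else is vectorised R. Every estimator is checked
against an independent brute-force implementation (literal double loops,
explicit DFT sums) on 100+ random short signals at 1e-10 (exact counting)
or 1e-8 (floating pipelines).

## Preprocessing

Recordings are resampled to 128 Hz by frequency-domain interpolation with
reflective edge padding (polyphase resampling is available as an option),
then band-passed 0.5–40 Hz with a Hamming-window FIR designed by the
3.3/transition-bandwidth rule — 845 taps at 128 Hz, with transition bands
min(max(f/4, 2), edge distance) — applied forwards and backwards for zero
phase. The zero-phase property is tested (a symmetric pulse keeps its peak
index), as are the band edges (a 0.1 Hz drift is attenuated by more than
40 dB after the two passes; a 10 Hz tone by less than 0.1 dB).

Artifact handling works on 1-s epochs: near-flat epochs are removed when
the peak-to-peak amplitude is below 1 uV on *every* channel (a single flat
channel is a channel problem, not an epoch problem — the rule is the max
across channels). Remaining epochs pass through a cross-validated
cleaning stage: per-channel peak-to-peak rejection thresholds are chosen
from a quantile grid by K-fold CV minimising the distance between the
mean of retained training epochs and the pointwise median of held-out
epochs; epochs with few supra-threshold channels are repaired by
inverse-distance-weighted interpolation from the three nearest channels
(hard-coded 2-D 10–20 layout); epochs with more than kappa bad channels
are rejected; (rho, kappa) come from a small grid on the same objective.
This is a deliberately transparent, desk-scale cleaning stage with the
same interface contract as heavier repair algorithms (learned per-sensor
thresholds, bounded repair, rejection); those remain pluggable. Clean 1-s
epochs are reassembled into 5-s analysis epochs from maximal consecutive
runs; a full clean minute yields exactly 12, and shorter sets are returned
short with a warning rather than failing, because cleaning-path tests need
exactly that behaviour. When both states of a subject survive with unequal
epoch counts the matrices are truncated to the common count.

Epoch pairing for the dynamic contrast is positional (epoch i with epoch
i). The two one-minute segments are selected independently from separate
clinical periods, so no physiological alignment exists to recover; index
pairing is a convention and is documented as such.

## Statistics

Group comparisons use the Mann–Whitney U test on per-subject means (the
reduction is the mean over epochs, and over channels for the global
scope), with a tie-corrected, continuity-corrected normal z, two-sided p,
and the rank-biserial effect size r = 1 - 2U/(n1 n2). Per-channel maps are
FDR-adjusted by Benjamini–Hochberg across the 17 channels within one
measure and state — not across measures. Normality screening uses the
Kolmogorov–Smirnov test against a normal with sample mean and SD; with
estimated parameters this screen is conservative under normality, which
the tests document rather than hide. Demographics: Welch's t for age and
the 2x2 chi-square for sex, with the Yates continuity correction on by
default — the corrected statistic is what the printed value for the
printed margins corresponds to (6.81 rather than the uncorrected 8.13) —
and the uncorrected variant behind a flag.

## The LOSO harness and its leakage contract

Each fold holds out one subject. Inside the training fold, in order:
subject-level random undersampling to balance classes (whole subjects
only, preserving 12-row blocks), per-channel z-scoring with train-only
parameters applied unchanged to the held-out subject, optional
entropy-configuration selection by inner AUC, hyperparameter tuning by
subject-grouped, class-stratified 5-fold CV on mean epoch-level AUC,
permutation channel importance (each channel shuffled within the
validation fold, 10 repeats, importance = mean AUC drop), retention of
channels positive in **every** inner fold (the stricter reading of
"consistently positive"; overall-mean-positive is available as an option;
if nothing qualifies the single best channel is kept with a warning),
threshold calibration by maximising sqrt(sensitivity x specificity) on
the pooled inner out-of-sample scores (no refit — reusing inner
validation scores is the choice here), a final refit on the whole
training fold, and a hard vote over the 12 epoch labels, with a 6-6 tie
broken by the subject's mean score against the threshold. Confusion
counts pool over folds.

Decisions worth making explicit because they were genuinely open: AUC is
computed at epoch level within subject-grouped folds (grouping prevents
subject leakage; epoch level keeps the score resolution); classifier
backends are established library implementations, not re-implementations,
because the contribution is the harness; every stochastic step consumes a
fold-derived seed, so whole experiments are bit-reproducible.

The leakage contract is tested directly: multiplying and shifting the
held-out subject's raw feature rows changes *no* training-derived
artifact — scaler parameters, retained subject set, tuned
hyperparameters, selected channels, threshold — bitwise.

## The synthetic cohort: what it emulates and what it does not

Each channel is a mixture of 1/f-coloured noise (slope beta = 1) and an
alpha-band sinusoid (10 Hz with per-subject jitter of SD 0.5 Hz, random
phase), scaled to 20 uV SD. The sinusoid mixing fraction is the
complexity knob: raising it makes the signal more periodic and lowers
every irregularity measure monotonically, which makes the generator easy
to validate against brute-force entropy oracles. Subjects draw a baseline
fraction from a Beta distribution with mean 0.30 and SD 0.06 — enough
between-subject variance that leave-one-subject-out evaluation is
meaningful rather than trivial. PNES preictal recordings add
`effect x spatial_profile[channel]` to the fraction; ES subjects and PNES
interictal recordings share one law, so `effect = 0` produces a fully
exchangeable null cohort. Between-subject entropy variance has no
published clinical value to copy; the defaults were chosen once for
testability and are not tuned against outcomes.

What passing tests therefore show: the estimators are correct, the
statistics are calibrated, the harness is leakage-free and recovers a
built-in state-dependent complexity shift with the expected topography
and the expected dynamic > preictal/interictal ordering. What they do not
show: performance on clinical EEG, which carries artifacts, nonstationary
rhythms, volume conduction and referencing structure the generator does
not model (eye/muscle artifacts appear only as optional test transients;
there is no volume-conduction model).

## Numerical and I/O choices

Undefined sample entropy (zero matches) propagates as `NA` and is
excluded from subject summaries with a logged count. Zero-variance
signals return entropy 0 by convention everywhere; zero-SD channels in
the scaler get SD 1 with a warning. Threshold-calibration ties break
toward 0.5. The EDF writer uses a symmetric digital range (-32767..32767)
so constant channels round-trip exactly, and the round-trip error of any
signal is bounded by the header-derived quantisation step; group/state
labels travel in a JSON sidecar. Config files are YAML with unknown keys
rejected by name; analyses checkpoint per measure/state/classifier unit
and re-runs resume from completed units; output tables embed the config
hash.

## Problem sizes used by the test and acceptance suites

Estimator oracles run on 100+ signals of 30–60 samples. Calibration and
recovery suites use 20+20-subject cohorts at the full one-minute,
17-channel geometry — three null seeds for calibration (mean LOSO balanced
accuracy asserted within [40, 60]%, a per-seed value being binomially
noisy at n = 40), one effect-0.4 cohort concentrated on O1/O2 for
recovery — with spectral entropy for the null suite and sample entropy
(m = 2, r = 0.2) for recovery. Generator-law properties (null centring,
monotonicity in the effect size, spatial fidelity) use many tiny cohorts
(2–6 subjects per group, 2–10 s states) against brute-force oracles.
These sizes are the package's chosen trade-off between statistical
resolution and a test suite that stays pleasant to run.

## Known limitations

The cleaning stage is a transparent approximation, not a reimplementation
of published Bayesian-optimised repair; multiscale entropy, approximate
entropy and SVD entropy are out of scope; the dynamic pairing is
positional; EDF support covers the plain 16-bit variant only (no EDF+
annotations); and synthetic validation bounds what can be claimed about
clinical generalisation, as above.
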