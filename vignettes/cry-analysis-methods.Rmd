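---
title: "Methods: cry acoustics and stacked random-forest assessment of NOWS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cry acoustics and stacked random-forest assessment of NOWS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Neonatal opioid withdrawal syndrome (NOWS) is assessed at the bedside with
observer-rated scales such as the Finnegan Neonatal Abstinence Scoring Tool
(FNAST; 21 items, range 0–46, pharmacological treatment triggered by a
score of 8 or more on two consecutive 3-hourly assessments or 12 or more
once). Crying features prominently in these scales but is rated
subjectively. Cry *acoustics* — fundamental frequency and hyperphonation,
formant frequencies, band energies, fricative turbulence, spectral entropy
and novelty, and the amount of crying itself — are objective correlates of
the same brain-stem and autonomic pathophysiology, and a cross-validated
machine-learning pipeline over those acoustics can predict which infants
go on to receive pharmacological treatment.

`crywatch` implements that pipeline end to end: frame-level acoustic
analysis under two analyzer profiles, utterance segmentation and two-level
summarization, feature filtering, ensemble Boruta selection inside
leave-one-out cross-validation (LOOCV), four stacked probability forests
(analyzer × utterance stratum), and diagnostic evaluation. Because no
clinical recordings are distributed, the package also ships a synthetic
cry-audio cohort generator that provides ground truth for every stage.

## The synthetic cohort generator

Utterances are produced by a source–filter model: a glottal impulse train
following a rise–fall pitch contour (base f0 ≈ 450 Hz; hyperphonation
episodes jump the fundamental above 1 kHz with a flattened contour), mixed
with aspiration noise (default 0.15 of the pulse amplitude — newborn cries
are breathy, and the inter-harmonic spectral support this creates is also
what makes linear-prediction formant estimation well-posed), filtered
through cascaded second-order resonators (F1 ≈ 1100 Hz, F2 ≈ 3300 Hz).
With a configurable probability a stretch of the utterance is replaced by
band-limited (2.5–8 kHz) turbulence noise standing in for fricatives.
Recordings concatenate utterances (250–900 ms) with inspiratory silence
gaps (200–600 ms); the background-noise floor (default SNR 25 dB) covers
gaps as well, so segmentation thresholds are meaningfully exercised. The
default sample rate is 22 050 Hz; infant cry energy lies below ~11 kHz.

The default cohort structure mirrors the study design the analysis
assumes: 19 neonates treated for NOWS, 7 opioid-exposed neonates who did
not develop NOWS, and 39 unexposed neonates (65 in all), with the treated
flag defaulting to NOWS-subgroup membership. A FNAST series simulator
(AR(1) noise around a severity-dependent mean, the treatment rule applied
exactly) is provided as an alternative labelling path but is not the
default.

Group differences are injected through an *effect map*: standardized mean
shifts per feature family. The source study reports which families
discriminated (hyperphonation, F1/F2, energies, utterance counts,
fricatives, entropy, novelty) but not their effect sizes, so the defaults
are generator settings chosen once — moderate-to-strong shifts (0.3–1.2
SD) concentrated on those families — to produce a separable but imperfect
cohort. In `feature_table` mode the infant-level tables are drawn directly
from Gaussian family distributions with those shifts (this is the mode
used for the classifier-level simulations; it recovers the requested
Cohen *d* exactly in expectation). In `audio` mode the shifts are applied
on the synthesis-parameter scale (higher hyperphonation probability,
shifted f0/F1/F2, more utterances, more fricatives); energy, entropy,
novelty and envelope effects are not injected in audio mode because
per-recording normalization would confound them.

What the generator does *not* emulate: perceptually realistic cry
quality, inspiratory sounds, adult speech or environmental contamination,
real missing-data mechanisms, or the correlation structure of real
analyzer feature inventories. Passing tests on synthetic cohorts
demonstrates that the pipeline is implemented correctly and behaves as
designed under known ground truth — not that the classifier would reach
any particular accuracy on clinical recordings.

## Acoustic front end

Both analyzer profiles share the frame geometry: 12.5 ms frames, half-
frame (6.25 ms) hop, Hann taper, giving frame length
`round(12.5·sr/1000)` samples and `floor((N − frame)/hop) + 1` frames.

**Pitch.** A single-stage cepstral peak picker is unreliable at this frame
length for neonatal fundamentals: the formant quefrencies (≈ sr/1100
samples for F1) fall inside the 150–2500 Hz search band, and periods that
fall between sample lags lose most of their peak amplitude to
quantization, producing rahmonic (period-multiple) errors. Both profiles
therefore share a whitened period-candidate stage — linear-prediction
inverse filtering removes the formant envelope, the residual's
autocorrelation is searched in the lag band, and integer divisors of the
peak lag are checked so that subharmonic picks are corrected — and then
diverge: the *cepstral* profile refines the period on the real cepstrum
of the whitened frame, with voicing gated on cepstral peak prominence
(≥ 3 × the median band cepstrum level) plus a band-periodicity check; the
*spectral* profile refines on the autocorrelation itself, with voicing
gated on the normalized peak (≥ 0.30). Peak positions are interpolated
parabolically. Hyperphonation is flagged when f0 exceeds a configurable
threshold, default 1000 Hz (the classical cry-literature definition; the
quantity has no standard numeric definition otherwise). Unvoiced frames
carry missing f0 — missingness is meaningful and is summarized downstream.

**Formants.** Voiced frames are pre-emphasized (0.97), low-pass filtered
and resampled to 10 kHz, and fitted with a Yule–Walker autoregressive
model of order 12. Poles with bandwidth < 400 Hz and frequency in
(200, 5000) Hz are resonance candidates; because short high-pitched
frames often split one resonance across two nearby poles, candidates
closer than 450 Hz are merged by bandwidth-weighted averaging before the
two lowest are taken as F1 and F2.

**Other features.** Band energies are decibel power sums split at
2500 Hz, floored at −120 dB. Spectral entropy is the Shannon entropy of
the normalized power spectrum over log(bins); note that for white noise
at 138 bins its expectation is ≈ 0.91, not 1 (the finite-bin shortfall is
(1−γ)/log nb for exponential periodogram ordinates). The fricative score
is a logistic combination of the high-band energy ratio and zero-crossing
rate, monotone in both. The amplitude envelope is per-frame RMS, its
modulation frequency the strongest non-DC spectral peak subject to a
3×-median prominence floor. Spectral novelty correlates a cosine
self-similarity matrix of the frame spectra with a 16-frame
Gaussian-tapered checkerboard kernel along the diagonal.

The two profiles differ in feature sets (the cepstral profile carries the
band energies and fricative score; the spectral profile carries entropy,
novelty and the envelope) and in the pitch refinement, emulating the
multiplicity of analysis systems that the stacking architecture was
designed for; the exact feature inventories of the original proprietary
analyzers are not public and are not reproduced.

## Utterances and summarization

A cry utterance approximates one expiratory vocalization: a maximal run
of frames whose total energy exceeds the recording's noise floor (10th
percentile of frame energy) by 15 dB, merged across gaps shorter than
50 ms, discarded when shorter than 50 ms or less than 30% voiced (the
voicing criterion stands in for the expiratory-phase restriction, since
inspiratory sounds are mostly unvoiced and short). None of these values
is prescribed by the study; they were chosen once to recover synthetic
ground truth and are exposed in `seg_config()`. Utterances are stratified
at 500 ms into short and long, the boundary value going to *long*.

Each utterance row holds, per feature, the mean over non-missing frames
and the missing-data rate; each infant row is the *unweighted* mean over
utterance rows (the study says only "means"; duration weighting is a
documented alternative, not the default), plus the utterance count. Four
tables result — {cepstral, spectral} × {short, long} — aligned on infant.

## Feature filtering

Before selection, features are removed for (in order) missing-data rate
strictly above 60%, near-zero variance (frequency ratio ≥ 19 with under
10% distinct values — the common preprocessing convention, since the
criterion itself is not printed in the study), and excessive
intercorrelation (pairwise-complete |r| strictly above 0.75, removing
greedily the member of the worst pair with the larger mean absolute
correlation, earlier column on ties). Filtering is applied once to the
full table by default, matching the study's stated data-reduction order;
because that leaks marginal information across LOOCV folds, a
`within_folds` switch moves the filter chain inside each fold.

## Selection: Boruta and the retention ensemble

The Boruta selector is implemented natively: each iteration appends a
permuted shadow copy of every active feature (padded to at least five
shadows), fits a random forest and records permutation importances; a
feature scores a hit when it beats the best shadow, and cumulative hits
are tested two-sided against Binomial(t, ½) at α = 0.01 with Bonferroni
correction over features. Significant excess confirms, significant
deficit rejects (rejected features leave the forest), and features still
undecided at the iteration cap stay *tentative*. Tentative counts as not
selected for the ensemble tally, since the retention rule speaks only of
selected variables. The ensemble repeats Boruta (default 100 times, seeds
derived from a master seed) and retains features confirmed in strictly
more than 5 runs. Stability is the percentage of LOOCV folds in which a
feature was retained; together with mean permutation importance it forms
the feature-stability profile and plot.

## The stacked classifier under LOOCV

For every infant, the full modelling procedure is repeated on the
remaining infants: per table, training-median imputation, ensemble
selection on training rows only, and a probability forest (default
10 000 trees, `mtry = floor(sqrt(p))`, minimum node size 10) on the
retained features. The held-out infant's stacked probability is the
unweighted mean of the available per-table probabilities. Three edge
policies are deliberate: an infant with no usable rows (zero utterances
everywhere) is excluded from evaluation; an infant whose available
tables all lost their model (no feature retained in that fold) receives
the uninformative probability 0.5 rather than a training-prevalence
value, because under LOOCV the training prevalence is negatively
correlated with the held-out label and would bias null-data AUC below
0.5; and an infant missing one stratum is averaged over the models that
exist (a fixed-0.5 substitution for missing models is a config
alternative, not the default).

All randomness fans out from one master seed through a stable arithmetic
hash (`derive_seed`), so a full run is bit-reproducible at fixed
configuration.

## Evaluation

The ROC curve thresholds at the distinct stacked probabilities; AUC is
the Mann–Whitney concordance with ties counted ½, its confidence interval
from the DeLong placement variance. The operating cutpoint minimizes the
Euclidean distance to the perfect-prediction corner, ties resolving to
the lower (more sensitive) threshold. Diagnostic proportions carry exact
Clopper–Pearson intervals — chosen because the published intervals for
17/19 and 38/40 match the beta-quantile bounds at two decimals — and
Cohen's κ carries the asymptotic standard-error interval
(√[p₀(1−p₀)/(n(1−pₑ)²)]). Zero-denominator ratios are reported missing.
Subgroup sensitivity analyses recompute the ROC, cutpoint and all
diagnostics on the retained stacked predictions (no refitting) after
excluding either the unexposed or the exposed-without-NOWS subgroup.
Group comparisons use Welch's t with Satterthwaite degrees of freedom and
pooled-SD Cohen's d (reported as a magnitude) for numeric covariates and
Pearson's χ² (with continuity correction on 2×2 tables) otherwise.

## Problem sizes and numerical choices

The paper-faithful defaults (100 Boruta repetitions, >5/100 retention,
10 000-tree forests) are impractical for routine simulation, so the
package's simulation studies run reduced configurations and rely on two
verified facts: selection behaviour is governed by the hit-test
statistics, not the repetition count, and test-set AUC at 500 trees is
within 0.02 of AUC at 10× more trees on these problems. The shipped
checks use: strong-effect cohorts (65 infants, d = 1.5 on five families)
with 2-run ensembles, 14-iteration Boruta, 50-tree selection forests and
500-tree classifiers, 5 seeds; null cohorts of 26 infants with 1-run
ensembles over 20 seeds; type-I checks on 100 × 10 noise tables over 20
seeds; and effect-size recovery at 500 infants per group averaged over
the four tables. Boruta's Bonferroni-corrected binomial test implies a
minimum run length for any decision (about 12 iterations at α = 0.01
with ~14 features), which the iteration caps respect.

Numerical edge handling worth knowing: all-zero frames yield −120 dB
energies, missing entropy and unvoiced pitch; formant estimation returns
missing when fewer than one or two qualifying resonances survive; the
correlation filter treats undefined pairwise correlations as zero; and
empty utterance sets aggregate to a zero-count, all-missing infant row.

## Limitations

The acoustic front end is a faithful member of the named feature
families, not a reimplementation of either proprietary analyzer, and the
synthetic cohort cannot certify clinical performance. Probability
calibration, misclassification-cost-weighted thresholds and alternative
selectors are intentionally out of scope. The pre-CV filter default
reproduces the study's stated order at a known (documented) leakage
cost.
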