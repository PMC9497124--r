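---
title: "Multimodal MCI screening: models, parameters, and design choices"
author: "cogniscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal MCI screening: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cogniscreen)
```

# The screening problem

Mild cognitive impairment (MCI) sits between normal aging and dementia;
identifying it at the community level calls for instruments that are
cheap, fast and non-invasive. This package implements a screening
pipeline over three such instruments — single-channel EEG, desktop eye
tracking (ET), and a neuropsychological test battery (NTB) plus basic
clinical variables — and a support-vector-machine classifier that fuses
them. Sensitivity is defined for detecting MCI: the positive class is
MCI (+1), controls are −1, throughout.

This vignette documents the models and every consequential default, the
reasoning behind design choices that were genuinely open, and what the
synthetic cohorts used in the test suite do and do not establish about
real data.

# EEG chain

**Validation.** A recording is excluded (never repaired) when the
electrode was evidently offset: any run of samples pinned at the
amplifier rail (|x| ≥ 95 % of a 200 µV full scale) or exactly flat for
at least 1 s. Runs shorter than the threshold are treated as transient
artifacts and left to the filters.

**Denoising.** A second-order Butterworth band pass at 0.5–30 Hz plus a
second-order band stop at 50 ± 2 Hz for power-line noise. Both are
applied forward–backward (zero phase): the filter order is the stated
one, the effective attenuation doubles, and event timing is preserved
for segment alignment. The 50 Hz default reflects a 50 Hz mains region
and is configurable; muscle and cardiac artifacts beyond the reach of
band filtering are out of scope.

**Segmentation.** A 5 s moving window with 60 % overlap (2 s step);
trailing partial windows are dropped. The segment count is data-driven:
`floor((L − 5)/2) + 1`. The generator's default recording length of
33 s is chosen so one recording yields the canonical 15 overlapping
segments; any length ≥ 5 s is accepted.

**Spectral features.** The power spectral density is the Fourier
transform of the biased sample autocorrelation over all lags
(Wiener–Khinchin), which equals the periodogram of the zero-padded
segment; it is returned one-sided and power-conserving (the integral
equals the mean square). Band powers integrate the PSD over δ (0.5–4),
θ (4–8), α (8–13) and β (13–30 Hz); relative powers normalize by total
0.5–30 Hz power, and the α/θ ratio is always computed. The
(δ+θ)/(α+β) slowing ratio is available but off by default, since only
the α/θ ratio is a fixed part of the feature set.

**Nonlinear features.** Approximate entropy uses m = 2 and
r = 0.15·SD per segment — the standard operating point; the tolerance
is data-relative, making the statistic invariant to amplitude scaling.
Multiscale entropy coarse-grains by non-overlapping block means at
scales 1–10 and applies *sample* entropy (self-matches excluded) with r
fixed from the original series' SD, following the multiscale-entropy
literature rather than reusing ApEn inside the curve; scale 1 is
exactly SampEn, and the fixed-r convention makes white noise decay with
scale while 1/f noise stays flat — the signature the test suite checks.
Lempel–Ziv complexity binarizes at the median (robust to amplitude
outliers; mean thresholding is a config option), runs the LZ76
exhaustive parse, and normalizes the word count as c(n)·log₂(n)/n.
These kernels are quadratic in segment length and are implemented in
C++.

**Aggregation.** The study design is one feature vector per subject;
features are computed per segment and averaged, and segments where a
feature is undefined (e.g. an α/θ ratio over zero θ power) are excluded
from that feature's mean rather than poisoning it.

# Eye-tracking chain

Gaze is normalized to display coordinates and low-pass filtered at 5 Hz
(second order, zero phase) within each contiguous run of valid samples;
invalid samples are never interpolated at this stage. Blinks are
maximal validity gaps lasting 70–500 ms — the physiological range;
shorter gaps are tracker noise (interpolated), longer ones signal loss
(excluded). Fixations and saccades come from an I-VT rule on
central-difference velocity with a 0.5 normalized-units/s threshold:
viewing geometry is unknown for a generic display, so a degrees/s
threshold cannot be defined and the threshold is a config parameter.
Fixations under 60 ms are discarded.

"Sustained attention duration" admits several readings; here it is the
time span of the longest run of consecutive fixations whose centroids
stay inside the area of interest, with blinks and out-of-AOI fixations
breaking the run. The AOI defaults to the central half of the display
and is configurable; the definition is isolated in one function
(`computeETMetrics`) so alternative readings are one-line changes.
Scan-path complexity applies the same LZ76 kernel to the
median-binarized scan-path speed series.

# NTB, clinical block, and normalization

NTB tables are cleaned against declared per-subtest valid ranges:
out-of-range cells become missing (logged), and subjects missing more
than half the subtests are dropped. Raw NTB scores are min–max scaled
into [0, 1] and then all assembled features are z-transformed — in that
order, composing the two stated normalizations. Both transforms are fit
on training data only and applied unchanged to held-out data; the test
suite verifies that perturbing held-out rows cannot change any fitted
parameter. Missing values after assembly are median-imputed with
training-fold medians. Gender is one-hot encoded.

The clinical view includes MoCA-B and ACE-R as features. Both correlate
with the diagnostic label by construction (they are screening scores),
so the clinical model carries a circularity caveat; it is kept because
the four-model comparison is defined that way.

# MRMR feature selection

Relevance is the mean mutual information between the features of a set
and the class label; redundancy is the pairwise MI against the selected
set scaled by 1/|S|². Mutual information is the plug-in estimate in
bits; continuous features are discretized by equal-frequency (rank)
binning with 8 bins, which is robust to outliers and makes the ranking
invariant to monotone feature transforms. The greedy criterion as
displayed — a Θ over Δ fraction — is read as the quotient (MIQ)
criterion, with the difference (MID) form available as a switch; the
quotient is guarded by a machine-epsilon floor on Δ, so the first step
reduces to pure relevance. Ties break by column order. The number of
selected features k defaults to 20 and can be tuned on training folds;
selection is performed inside each cross-validation fold by default
(leakage-safe), with a global pre-selection available for comparison.

# Classification and evaluation

The SVM solves the usual soft-margin dual (0 ≤ αᵢ ≤ C) through libsvm;
the package orients decision scores so positive margins point to MCI
regardless of internal class ordering. The default configuration is
RBF with C = 1.1 and γ = 0.001; the grid search spans
{linear, poly, RBF, sigmoid} × C ∈ {0.1, 0.5, 1.1, 4, 17, 20} ×
γ ∈ {0.001, 0.01, 0.02, 0.1}, with ties broken toward smaller C and
simpler kernels.

Cross-validation is stratified at subject level with 5 folds; the whole
pipeline — imputation, normalization, MRMR, SVM — is refit inside each
training fold. Accuracy, sensitivity and specificity are reported as
fold mean ± SD in percent; the AUC uses the pooled out-of-fold decision
scores. AUC is computed as the rank (Mann–Whitney) statistic with ties
counted one half, which equals the trapezoidal area under the empirical
ROC, and its 95 % CI is a stratified bootstrap percentile interval with
2000 resamples — a method choice, since no CI method is canonical here.
The independent test cohort is evaluated single-shot (fit once on all
of cohort 1, never refit); because a single-shot evaluation has no fold
dispersion, the reported SD for the test cohort is a bootstrap SD over
test-cohort resamples, which is comparable in spirit but not in
mechanism to the CV fold SD.

# The synthetic cohort: what it emulates and what it does not

The generator produces, per subject: EEG as a sum of band-limited
Gaussian oscillations (baseline RMS amplitudes δ 6, θ 5, α 10, β 3 µV)
over a 1/f pink-noise floor (5 µV), optional 50 Hz line noise and
optional saturation bursts; eye tracking as a piecewise-stationary scan
path (lognormal fixation durations around 250 ms, ballistic saccades,
Poisson blinks at 15/min encoded as validity gaps); an NTB of 20
correlated subtests plus total score and response time; and
demographics with group-balanced age, gender and education.

Group differences enter through standardized latent shifts per feature
family: each subject draws a trait z ~ N(effect, 1) (effect 0 for NC)
that multiplies the family baseline by 1 + cv·z. The defaults encode
MCI-typical alterations of moderate size: α power −0.8 SD, θ power
+0.8, broadband complexity −0.6, fixation time +0.8, blink rate +0.5,
NTB scores −1.0. For MoCA-B and ACE-R the defaults (−0.5 and −0.4 SD)
deliberately produce a *weak* clinical model (AUC ≈ 0.65): published
marginal score gaps for screening instruments are far larger, but a
clinical model built from them would dominate every other modality,
which contradicts the observed behaviour of such models under
cross-validation; the generator targets the emergent model-comparison
behaviour rather than the marginal score gaps, and stronger shifts are
one config entry away.

Passing tests on these cohorts show that the pipeline recovers planted
effects, ranks multimodal fusion above single modalities when all
modalities carry signal, stays at chance when none does, and leaks
nothing from held-out data. They do not show field performance: real
EEG has nonstationarities, artifacts and inter-site variability; real
gaze has smooth pursuit, calibration drift and task structure; real
neuropsychological profiles are not Gaussian. Numbers obtained on
synthetic cohorts characterize the software, not the clinic.

# Numerical and degenerate-input policy

Relative band powers are undefined (missing, logged) at zero total
power; sample entropy returns NA when no template pair matches;
constant series have ApEn, SampEn and MsEn defined as 0; constant
feature columns are dropped with a warning at normalization and skipped
at MRMR; empty event classes yield 0 for rates and NA for means; MI
estimates clip floating-point negatives to 0. Determinism: every
stochastic step (cohort generation, fold assignment, bootstrap) derives
its seed from a single master seed via stable string hashing, so a
fixed configuration reproduces reports byte for byte while stages stay
decoupled.

# Problem sizes in the test suite

The suite exercises oracle equivalence on sequences up to n = 500,
noise-colour signatures at n = 2000 over 10 seeds, a null cohort of
15 + 15 subjects over 20 seeds, and a strong-effect cohort (1.5 SD
shifts in the EEG, ET and NTB families) of 150 + 150 subjects over 10
seeds; the acceptance script runs the full two-cohort comparison at
336 + 92 subjects. These sizes keep the complete suite within minutes
on a single CPU while leaving every statistical check comfortably
powered.

# Known limitations

Single-channel EEG only (no montages, no ICA-based ocular artifact
removal); no time–frequency or connectivity features; no gamma band (the
0.5–30 Hz pass band excludes it); no pupillometry beyond blink
detection or smooth-pursuit analysis; SVM is the only classifier; MI
estimation is binned plug-in (no kNN estimators); and the MRMR search
is greedy, not global.
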