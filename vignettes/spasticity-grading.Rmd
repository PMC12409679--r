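---
title: "Grading elbow-flexor spasticity from multichannel sEMG: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grading elbow-flexor spasticity from multichannel sEMG: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spastemg)
```

## The problem and the model

Spasticity — a velocity-dependent increase in muscle tone after an
upper-motor-neuron lesion such as stroke — is graded clinically on the
Modified Ashworth Scale (MAS), an ordinal scale whose reliability suffers
from examiner subjectivity. During passive elbow extension, a spastic
flexor's stretch reflex produces measurable surface EMG activity, and the
strength and spectral content of that activity track the MAS grade: more
spastic muscle produces larger-amplitude sEMG with spectral content shifted
toward lower frequencies. `spastemg` operationalizes that observation as an
automated grading pipeline over three elbow-flexor channels (LB, SB, BR):

1. segment each recording's active-movement span into thirds (A/B/C);
2. denoise each segment (band-pass 20–450 Hz, notch 48–52 Hz);
3. extract RMS, iEMG, envelope area (EA), mean power frequency (MPF) and
   median frequency (MF) per segment and channel;
4. max–min normalize each feature/channel column over the sample population;
5. screen features by Spearman correlation with the MAS ordinal
   (|ρ| ≥ 0.7 on all channels);
6. fuse each retained feature's three channel values with
   correlation-proportional weights ωᵢ = rᵢ/(r₁+r₂+r₃), e = Σωᵢeᵢ;
7. classify the fused vectors with k-NN, selecting K by stratified
   10-fold cross-validation and reporting an aggregated confusion matrix,
   per-class precision/recall/F1, and baseline comparisons.

The modelling assumptions are explicit: the grade–feature relationship is
monotone (hence rank correlation for screening and weighting), channels are
redundant but not identical (hence a convex channel combination can beat
any single channel), and classes are represented well enough locally that a
nearest-neighbour vote is meaningful on a balanced design of 40 samples per
grade.

The MAS labels 0, 1, 1+, 2, 3 are encoded as ordinals 0–4. Grade 4 (limb
rigid in flexion/extension) is outside the model: patients at that level are
rarely testable with this passive-movement protocol, and the encoder rejects
the label rather than silently extrapolating.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| band-pass edges | 20–450 | Hz | the sEMG energy band at 1024 Hz sampling; removes drift/motion artifact below 20 Hz and noise above 450 Hz |
| notch band | 48–52 | Hz | powerline interference at 50 Hz |
| filter orders | 4 (band-pass), 2 (notch) | — | standard Butterworth orders; forward–backward application squares the magnitude response |
| screening threshold | 0.7 | \|ρ\| | "strong" correlation; with published clinical coefficients it keeps exactly the time-domain features |
| samples per grade | 40 | — | the balanced design (200 samples total from 240 available segments) |
| folds | 10 | — | 20 held-out samples per fold, 4 per grade |
| K grid | odd 1–13 | — | odd values avoid binary vote ties; 13 ≈ sqrt of the training-set size caps neighbourhood size |
| fusion mode | `paper_global` | — | weights from the full population; `fold_safe` recomputes them per training fold |

## Numerical choices

**Filters.** The band edges and notch band are fixed by the protocol; family
and order are not, so we use 4th-order Butterworth band-pass and 2nd-order
Butterworth band-stop, both applied forward–backward (zero phase) so that
burst timing — which the envelope feature integrates — is not delayed.
`signal::filtfilt` does not pad, so each signal is extended by ~1 s of
odd-reflected samples at both ends before filtering and trimmed after;
this suppresses the startup transient of the 20 Hz edge. Linearity, length
preservation, passband flatness (100 Hz within ±5%), stopband attenuation
(DC < 1%, 500 Hz < 0.1, 50 Hz ≥ 40 dB down) and burst-peak preservation
(±5 samples) are asserted in the test suite.

**Segmentation.** Sample intervals are 0-based and half-open, so a span
partitions without ambiguity. When the span length is not divisible by
three, the remainder goes to the earliest segments — a fixed tie-break that
keeps lengths within one sample.

**Envelope area.** Strict local extrema (sign change of the first
difference) are interpolated by a natural cubic spline, with the first and
last raw samples anchored into both extrema lists so the spline never
extrapolates beyond the data. The area is the absolute value of the signed
trapezoidal integral of each envelope (dt = 1 sample), summed over upper
and lower envelopes — the absolute value sits outside the integral, so an
envelope that changes sign contributes its net, not total, area; this is
the definition the pipeline is built around. Natural-spline ripple near the
anchored endpoints decays within a few inter-extremum intervals and is
negligible for the 10⁵-sample clinical segments. The sample-index units of
iEMG and EA (no 1/rate factor) are immaterial because every feature is
max–min normalized before use.

**Spectra.** MPF and MF need a power spectral density; we use a
Welch-averaged periodogram (1-s Hann windows, 50% overlap), the standard
estimator for sEMG spectral summaries, normalized so the integrated density
matches the mean square power (checked to 5% in tests). MPF is the discrete
spectral centroid; MF is the first bin where cumulative power reaches half
the total, so both are accurate to one spectral bin (1 Hz at the defaults).

**Normalization population.** Features are normalized over the full
balanced sample set, and the default fusion mode likewise estimates
correlations and weights once from all samples — mirroring a global-table
analysis. That choice leaks label information into cross-validation folds,
so a `fold_safe` mode recomputes the weights from each fold's training
part only; the correlation *screen* stays global in both modes so that the
fused feature space has the same dimension in every fold. A degenerate
(constant) feature column raises an error rather than normalizing to an
arbitrary constant: it signals a broken extraction.

**Fusion.** Weights are computed from signed correlations. After the
magnitude screen, a surviving feature correlates with the same sign on all
three channels in any realistic dataset; a guard rejects mixed-sign triples,
for which the weighted sum would not be a convex combination. With
nonnegative weights the fused value always lies between the channel minimum
and maximum (property-tested).

**k-NN determinism.** Euclidean distance; neighbour ties at the K-boundary
are resolved by stable sample order; vote ties by the tied class of the
nearest neighbour; residual exact-distance ties by the lowest MAS ordinal.
Every prediction is therefore reproducible bit-for-bit, and the
implementation is checked against an independently coded brute-force
enumerator on hundreds of random small datasets.

**Cross-validation bookkeeping.** Folds are stratified (4 per grade per
fold on the balanced design); fold confusion matrices are summed, so each
sample is predicted exactly once and per-class TP+FN equals the per-grade
sample count; mean accuracy is the average of per-fold accuracies, which
equals pooled accuracy for equal-sized folds. All seven comparison models
(three single-channel, three single-feature, fused) are evaluated under one
shared fold assignment.

## The synthetic cohort: what it emulates, and what it does not

The generator reproduces the recording protocol exactly: 2 min rest, then
3 loops of 3 consecutive 30-s flexion–extension cycles (each cycle = three
contiguous ~10-s movements) with 30-s breaks between loops, then 2 min
rest, at 1024 Hz. The default cohort is 8 patients per grade × 2 trials,
giving 240 segment samples of which 40 per grade are selected — the
balanced 200-sample design. The active span emitted in the manifest runs
from the first loop's start to the last loop's end; it necessarily contains
the two interior breaks, and its thirds each contain exactly one full
90-s loop (three movement sets), which is what the segment definition
requires.

The signal model is amplitude-modulated band-limited Gaussian noise, not a
motor-unit simulation: during movement epochs each channel carries
Hann-enveloped noise band-passed to 30–250 Hz, with the upper band edge
lowered by 30 Hz per grade step (band centre −15 Hz per grade) and the RMS
gain increasing strictly with grade (defaults 0.05, 0.10, 0.18, 0.30,
0.50 mV). Baseline Gaussian noise (0.01 mV) and a common-phase 50 Hz
powerline tone (0.05 mV) are added everywhere. Two multiplicative
log-normal factors create realistic dispersion: a per-patient gain
(sd 0.2) and a per-channel jitter (sd 0.1) that makes the channels
imperfectly correlated, so fusion has independent noise to average away.
All draws descend from one master seed through a deterministic per-recording
seed plan, so streaming and materializing the cohort give identical data.

This emulates the *statistical structure* the analysis relies on — a
grade-monotone amplitude relationship, grade-decreasing spectral content,
powerline contamination, within-grade variability — but not the physiology:
no motor-unit action-potential shapes, no stretch-reflex threshold dynamics,
no velocity dependence, no electrode-placement or skin-impedance effects,
and effect sizes that are free parameters rather than measured quantities.
Consequently, passing tests demonstrate that the pipeline recovers planted
structure and that its bookkeeping is correct; absolute synthetic accuracies
say nothing about accuracy on clinical recordings, and the generator's
strong defaults make the synthetic classes nearly separable.

## Problem sizes used in the test suite

The structure-recovery checks run the full default cohort (80 recordings of
the complete 9.5-min protocol, 720 segment-channel feature rows, 200
selected samples), which takes on the order of two minutes. All other tests
use a shortened protocol configuration (seconds-long rests and cycles, the
same signal model and code paths) or closed-form fixtures, so the rest of
the suite completes in well under a minute.

## Known limitations

- The envelope-area definition (absolute value outside the integral) makes
  EA nearly proportional to iEMG for symmetric zero-mean bursts; on real
  data the two carry largely redundant information, which matches their
  near-identical correlation behaviour.
- The magnitude screen and signed-weight formula assume a monotone
  grade–feature relationship; features with genuinely mixed per-channel
  correlation signs are rejected rather than fused.
- `paper_global` mode is optimistic in cross-validation because weights
  (and the normalization) see all labels; `fold_safe` quantifies that
  leakage for the weights but keeps the screen global.
- MAS grade 4 and non-elbow muscle groups are out of scope; the file format
  is a plain three-column CSV at a fixed channel order, not a vendor format.
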