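# spastemg

Automated grading of post-stroke elbow-flexor spasticity on the Modified
Ashworth Scale (MAS) from three-channel surface electromyography (sEMG).

## Who this is for

Rehabilitation researchers and biomedical engineers who record sEMG from the
long head of the biceps brachii (LB), the short head of the biceps brachii
(SB) and the brachioradialis (BR) while a clinician passively flexes and
extends the patient's elbow, and who want an objective, reproducible MAS
grade (levels 0, 1, 1+, 2, 3) instead of a purely manual rating. The package
also ships a synthetic-cohort generator that emulates the full recording
protocol, so the entire pipeline can be exercised and validated without any
clinical data.

## The method

For each recording (1024 Hz, three channels), the active-movement span is
split into three equal segments A/B/C, each segment is denoised with a
20–450 Hz Butterworth band-pass and a 48–52 Hz notch (both zero-phase), and
five features are computed per segment and channel:

- **RMS** — root mean square amplitude, `sqrt(mean(x^2))`;
- **iEMG** — integrated EMG, `sum(|x|)`;
- **EA** — envelope area: natural cubic splines are interpolated through the
  signal's local maxima (upper envelope *L(t)*) and minima (lower envelope
  *l(t)*), and `EA = |∫L(t)dt| + |∫l(t)dt|` by trapezoidal integration;
- **MPF** — mean power frequency, the centroid `Σ fᵢPᵢ / Σ Pᵢ` of a
  Welch-averaged power spectrum;
- **MF** — median frequency, where cumulative spectral power reaches half
  the total.

Features are max–min normalized to [0, 1] across the balanced sample
population, then screened by Spearman correlation with the MAS ordinal: a
feature is kept only if |ρ| ≥ 0.7 on all three channels (with published
clinical data this keeps RMS, iEMG and EA and drops MPF and MF). For each
retained feature, the three channels are fused into a single value

    e = ω₁e₁ + ω₂e₂ + ω₃e₃,   ωᵢ = rᵢ / (r₁ + r₂ + r₃),

where `rᵢ` is channel *i*'s Spearman correlation with the MAS grade. The
fused three-dimensional feature vectors feed a k-nearest-neighbour
classifier (Euclidean distance, majority vote, deterministic tie-breaks);
K is selected over the odd grid 1–13 by stratified 10-fold cross-validation,
and the model is evaluated by an aggregated confusion matrix with per-class
precision/recall/F1, alongside single-channel and single-feature baseline
models compared under identical folds.

## Worked example

Channel weights from published RMS–MAS Spearman coefficients
(LB 0.80, SB 0.83, BR 0.78):

```r
library(spastemg)
w <- compute_weights(c(0.80, 0.83, 0.78))
round_half_up(w, 2)
#> [1] 0.33 0.34 0.32
```

The LB/SB/BR channels contribute 33%, 34% and 32% of the fused RMS value —
weights proportional to how strongly each muscle's RMS tracks the grade.

End to end on a small synthetic cohort (shortened protocol, 4 patients per
grade, 2 trials each → 120 segment samples):

```r
cfg <- synth_config(n_patients_per_grade = 4, trials_per_patient = 2,
                    rest_duration = 2, cycle_duration = 3, cycles_per_loop = 2,
                    loops = 2, break_duration = 2, movement_duration = 1)
ft  <- cohort_features(cfg)            # preprocess + segment + extract
run <- run_pipeline(ft, per_grade = 20, folds = 5, seed = 1)
round(run$correlations, 2)
#>     rms iemg   ea   mpf    mf
#> LB 0.95 0.91 0.92 -0.98 -0.98
#> SB 0.96 0.92 0.92 -0.98 -0.97
#> BR 0.96 0.92 0.92 -0.98 -0.98
```

The generator plants the clinically observed structure — amplitude features
rise with grade (strong positive ρ), spectral features fall (negative ρ) —
and the pipeline recovers it. The run report then shows the cross-validated
confusion matrix, per-class precision/recall/F1, and the model comparison:

```r
run
#> Model comparison (mean CV accuracy):
#>   channel_LB      91.0%
#>   channel_SB      89.0%
#>   channel_BR      92.0%
#>   feature_rms     87.0%
#>   feature_iemg    77.0%
#>   feature_ea      73.0%
#>   fused          100.0%
```

On synthetic data the fused model outperforms every single-channel and
single-feature baseline; absolute accuracies depend on the generator's
effect sizes and are not comparable to clinical results.

A command-line front end (`inst/scripts/semg-grade.R`) wraps the same
functions as `simulate`, `run` and `metrics` subcommands for shell use.

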