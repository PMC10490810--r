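# ecgbeat

Single-lead ECG analysis in R: from raw voltage trace to fused
arrhythmia-beat classification. The package is aimed at people building
or evaluating automated heartbeat classifiers — it provides every stage
of the chain as a tested, composable function, plus a synthetic-record
generator so the whole pipeline runs and is verifiable without any
external database.

The stages:

1. **Synthetic annotated ECG** — beats as sums of Gaussian sub-waves
   (P, Q, R, S, T) with per-class templates (normal, left/right
   bundle-branch block, ventricular premature, atrial premature,
   fusion), rhythm presets from resting sinus (60–100 BPM) to atrial
   fibrillation (300–600 BPM), and additive Gaussian / powerline /
   baseline-wander noise.
2. **I/O** — a plain CSV dialect (`fs=<Hz>` header + one mV sample per
   line, annotation sidecar) and WFDB records (formats 212 and 16, MIT
   annotation files).
3. **Denoising** — periodized multilevel wavelet transform with
   soft/hard universal-threshold shrinkage
   (threshold `σ√(2 ln N)`, `σ = median(|d₁|)/0.6745`), and
   quantitative basis selection by MAE with SNR tie-break over
   bior2.6 / db8 / sym8.
4. **QRS detection** — the dual-slope transform
   `S_diff,max = max(S_L,max − S_R,min, S_R,max − S_L,min)` over
   0.03–0.05 s slope windows, sliding integration, zero-phase low-pass
   merging of the bimodal response, and adaptive two-threshold peak
   acceptance (`H_cur > H_ave × 0.4`; `θ₀/θ₁` updated per peak with
   floors).
5. **Segmentation and labels** — 250-sample beats (100 before / 150
   from the R-peak), MIT-BIH 4-class (N, L, R, V) and AAMI 4-class
   (N, S, V, F; unclassifiable beats excluded) schemes, stratified /
   per-record / k-fold splits, and weight / oversample / undersample
   rebalancing.
6. **Models** — logistic regression, RBF SVM, gradient-boosted trees
   (eta 0.3, max_depth 6, lambda 5, alpha 3, colsample 0.9/0.9, seed
   2020) on morphological + wavelet-coefficient features; a 1-D CNN
   (kernels 11-3-3-3, two pools, FC 128-64-32-K, dropout 0.5) and an
   LSTM on raw beats, both implemented in the package and trained with
   Adam (lr 0.001, batch 64).
7. **Fusion** — hard/soft voting and five-fold stacking with
   out-of-fold meta-features and a logistic-regression meta-learner.

## Worked example

```r
library(ecgbeat)

# a noisy one-minute sinus record with ground-truth annotations
rec <- simulate_ecg("normal", duration = 60, seed = 42,
                    noise = noise_spec(gaussian_sd = 0.1, seed = 42))
rec
#> <ecg_record 'sim-normal'>  21600 samples @ 360 Hz (60.0 s), 77 annotations
#>   beats: N=77

# denoise, then detect R-peaks
den <- wavelet_denoise(rec$samples, rec$fs, basis = "bior2.6")
clean <- simulate_ecg("normal", duration = 60, seed = 42)
snr_db(clean$samples, rec$samples)   # 5.80 dB before
snr_db(clean$samples, den)           # 9.03 dB after
peaks <- detect_qrs(den, rec$fs)
match_peaks(rec$annotations$sample, peaks, 9)
#> $tp: 77   $fp: 0   $fn: 0     (all 77 beats found within 25 ms)

# a labelled four-class beat set, features, and a boosted-tree classifier
bs <- synthetic_beat_set(150, seed = 7, noise_sd = 0.05)
feats <- beat_features(bs)
sp <- split_beats(bs, split_spec(test_fraction = 0.2, seed = 7))
fit <- train_beat_classifier(feats[sp$train, ], bs$labels[sp$train], "gbtree")
pred <- predict(fit, feats[sp$test, ], type = "class")
evaluate_predictions(bs$labels[sp$test], pred, c("N", "L", "R", "V"))
#> Overall accuracy: 100.00%  (n = 120)
#>  class  n correct accuracy
#>      N 30      30   100.00
#>      L 30      30   100.00
#>      R 30      30   100.00
#>      V 30      30   100.00
```

The numbers mean: denoising recovered ~3.2 dB of SNR at 0.1 mV noise;
the detector found every annotated beat with no false positives; and on
the well-separated synthetic templates a single classical model already
reaches 100% held-out accuracy (the interesting comparisons — model
families, fusion, noise levels — are in the test suite and the
acceptance script).

`run_pipeline(pipeline_config(seed = 1))` executes the whole chain
(simulate → denoise → detect → segment → features → five models →
voting + stacking → per-class reports) from one configuration list, and
`inst/exec/ecgbeat` exposes the stages as shell subcommands
(`simulate`, `denoise`, `detect`, `segment`, `evaluate`, `run`).

## Limitations

The synthetic generator reproduces the signal features the algorithms
key on, not clinical reality; accuracies on it validate the machinery,
not clinical performance. See the methods vignette
(`vignettes/ecgbeat-methods.Rmd`) for the model details, parameter
rationale and known limitations.
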