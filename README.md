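# nirsloc — decoding sound-source direction from fNIRS

`nirsloc` is an R package for block-design functional near-infrared
spectroscopy (fNIRS) studies of horizontal sound localization: does the
single-trial oxy-hemoglobin response over auditory and prefrontal cortex
carry enough information to tell where a sound came from?

It is written for auditory-neuroscience and BCI researchers working with
multichannel continuous-wave fNIRS. The package covers the full analysis
chain as tested, reusable functions:

* **modified Beer–Lambert conversion** of three-wavelength optical
  density to oxy-/deoxy-/total-Hb (`mbll_convert()`), solved per sample
  by least squares from ΔOD = ε·Δc·L;
* **preprocessing**: common average reference (`car_filter()`),
  zero-phase 4th-order Butterworth band-pass 0.03–0.2 Hz (`bandpass()`),
  stimulus-locked 10-s epoching at 13.3 Hz (`segment()`), averaging into
  the ten bilateral regions of interest of the 20-channel montage
  (`roi_average()`, `nirs_probe_map()`), grand-average curves with SEM
  (`grand_average()`);
* **windowed temporal features**: mean, variance, skewness, kurtosis and
  slope over a fixed 14-window grid spanning the 2–10 s response period
  (`extract_features()`, `window_grid()`);
* **decoding**: Fisher-criterion feature scoring
  FS_k = (μ₁−μ₂)²/(σ₁²+σ₂²) (`fisher_scores()`), leave-one-out linear-SVM
  classification over feature-set sizes 1–20 with strictly
  leakage-free per-fold selection and standardization (`loocv_svm()`,
  `decode_contrast()`), interhemispheric ipsi/contralateral ROI pairing
  (`pair_hemispheres()`) and per-ROI sound-level decoding
  (`sound_level_decoding()`);
* **behavioral scoring** for a seven-loudspeaker arc: RMS localization
  error in degrees, per-level reports and target-by-response confusion
  matrices (`rms_error()`, `rms_report()`, `response_matrix()`);
* a **seeded synthetic session generator** (`simulate_session()`) with
  double-gamma HRF block responses, per-ROI condition effects, cardiac /
  respiratory / drift / white / shared-global noise and a behavioral
  confusion model, so every stage is testable without recordings;
* **orchestration** of multi-subject simulated studies with summary
  tables and manifests (`run_config()`, `run_pipeline()`).

The methods vignette (`vignettes/sound-localization-decoding.Rmd`)
documents the model, the conventions (time-to-sample mapping, moment
definitions, degenerate-case handling) and the design decisions.

## Worked example

Simulate one subject under the committed lateral-effect preset, run the
preprocessing chain, and decode -90° versus +90° at 58 dB:

```r
library(nirsloc)

cfg  <- simulation_config(seed = 42, effects = effect_preset("lateral"),
                          behavior = behavior_model("lateral_confusion"))
sess <- simulate_session(cfg)
sess$recording
#> <nirs_recording> subject sim
#>   20 channels x 26733 samples (2010 s at 13.3 Hz), chromophore: oxy
#>   100 events

epochs <- preprocess_recording(sess$recording)   # CAR -> band-pass -> epochs -> ROIs
epochs
#> <nirs_epochs> 100 trials x 10 rois x 133 samples (13.3 Hz)

ft  <- extract_features(epochs)                  # 700 candidate features
res <- decode_contrast(ft, contrast_spec(-90, 90, 58, 58))
res
#> <decoding_result> n=20, best accuracy 85.00% at dim 20 (selection: per_fold)
#>   top selected features: u10:6-10s:kurtosis, u10:8-10s:variance, u2:5-9s:kurtosis

head(res$per_dim_accuracy, 8)
#>    1    2    3    4    5    6    7    8
#> 0.45 0.55 0.70 0.65 0.75 0.75 0.75 0.80

rms_report(sess$behavior)
#> RMS localization error: low 9.49 deg (n=50), high 7.35 deg (n=50), all 8.49 deg
```

Reading: the 20 trials of this contrast (10 per class) are classified by
leave-one-out cross-validation; with 20 folds, accuracies move in 5%
steps. Accuracy climbs as more Fisher-ranked features enter and peaks at
85% for this subject. The behavioral report shows this simulated
listener occasionally mistaking ±90° for ±60° (the confusion preset),
pooling to an 8.49° RMS error — the identity
rms_all² = (n_low·rms_low² + n_high·rms_high²)/n holds exactly.

Per-subject best accuracies across a simulated cohort are summarized
against the 70% practical margin with `summarize_accuracies()` and
compared between levels with `compare_conditions()` (one-way ANOVA or
paired Wilcoxon). The published per-subject accuracy and RMS tables of
the 25-listener study this pipeline reproduces are shipped as reference
data (`reference_accuracy_table()`, `reference_rms_table()`).

## Native data format

A session on disk is a directory of diffable text files: `header.yaml`
(sampling rate, chromophore, subject, dimensions), `signals.tsv`
(channels × samples), `events.tsv` (onset_s, location_deg, intensity_db,
duration_s), `channels.tsv` (probe map) and optionally `behavior.tsv`.
`write_recording()` / `read_recording()` round-trip losslessly;
`make_fixture_suite()` writes a seeded battery of test sessions
(null-effect, high-SNR lateral, intensity-only).

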