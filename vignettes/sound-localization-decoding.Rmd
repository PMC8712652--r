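---
title: "Decoding sound-source direction from fNIRS: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding sound-source direction from fNIRS: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirsloc)
```

## The experiment this package models

A listener sits at the center of a seven-loudspeaker arc spanning
-90° to +90° at 30° spacing. Pink-noise bursts are presented from five
active speakers (-90°, -30°, 0°, +30°, +90°) at two levels (48 and
58 dB SPL) in a block design: 10 s of stimulation followed by 10 s of
rest, 10 repetitions of each of the ten condition cells, 100 trials in
total, after a 10-s preparation period. During each block the listener
attends to the perceived direction and reports a speaker (1-7) at the
block's end. Cortical hemodynamics are recorded with a 20-channel
continuous-wave fNIRS montage (13.3 Hz sampling, three wavelengths)
covering premotor cortex (BA6), supramarginal gyrus (BA40), dlPFC (BA9),
superior temporal gyrus (BA22) and auditory association cortex (BA42) on
both hemispheres; channels are grouped into ten regions of interest
(`nirs_probe_map()`).

The analysis question is whether single-trial oxy-Hb responses carry
enough information to classify where the sound came from. The package
implements the complete analysis as reusable, tested functions, together
with a synthetic session generator so that every stage can be validated
without access to recordings.

Two entries of the shipped probe map look like transcription artifacts in
the source montage table (channel 6's X coordinate of -6 mm, and channel
17 duplicating channel 18's coordinates); they are retained verbatim and
have no effect on the analysis, which uses only the channel-to-ROI
partition.

## From light to hemoglobin

Continuous-wave instruments measure optical-density changes
$\Delta OD_\lambda$ at three wavelengths (780, 805, 830 nm). The modified
Beer–Lambert law relates them linearly to chromophore concentration
changes,

$$\Delta OD_\lambda = \left(\varepsilon^{HbO}_\lambda\, \Delta c_{HbO} +
\varepsilon^{HbR}_\lambda\, \Delta c_{HbR}\right) L,$$

with $L$ the effective pathlength. `mbll_convert()` solves this
overdetermined 3×2 system per sample by least squares; total hemoglobin
is the sum of the two solutions. Concentrations are carried in
pathlength-scaled units (mM·mm), the natural unit when the differential
pathlength factor is unknown. The extinction table
(`extinction_defaults()`) is an editable constant: only the inversion is
load-bearing, and a forward-projection/inversion round trip recovers
concentrations to better than 1e-10.

## Preprocessing chain

The chain follows the canonical order and operates on the continuous
recording only — never on epochs:

1. **Common average reference** (`car_filter()`): subtract the
   across-channel mean at each time point. Any component shared by all
   channels with coefficient one (global systemic physiology) is removed
   *exactly*; after CAR every column mean is zero to machine precision.
2. **Low-pass** 4th-order Butterworth at 0.2 Hz, suppressing cardiac
   (1–1.5 Hz) and respiratory (0.2–0.5 Hz) rhythms.
3. **High-pass** 4th-order Butterworth at 0.03 Hz, removing baseline
   drift.
4. **Epoching** (`segment()`): 10-s windows from each stimulus onset
   (133 samples at 13.3 Hz).
5. **ROI averaging** (`roi_average()`): arithmetic mean of each ROI's
   member channels.

Design choices that the analysis description leaves open, and how they
were fixed here:

* **Filter application.** Filters are applied zero-phase
  (forward–backward) by default. A causal pass of a 4th-order filter at
  these cutoffs delays the signal by seconds, which would shift the
  discriminative 5–8 s response window; zero-phase filtering avoids that
  at the cost of doubling the effective attenuation (documented: the
  composed chain attenuates 1.2 Hz by far more than the 40 dB contract).
  `filter_spec(application = "causal")` provides the literal
  single-pass alternative.
* **Epoch baseline.** Each trial is baselined by the per-channel mean
  over the second before the onset (`[-1, 0)` s). Grand-average curves
  then start near zero, matching how such responses are conventionally
  displayed; `baseline = "none"` gives the strictly literal segmentation.
* **Time-to-sample mapping.** At 13.3 Hz, second boundaries fall between
  samples. The rule is fixed once: sample index `round(t * fs)` (0-based)
  and half-open windows `[start, end)`. A 10-s epoch is therefore always
  exactly 133 samples.

## Feature extraction

Because hemodynamic responses peak with a variable 3–8 s delay, features
are computed over a grid of fourteen windows within the epoch
(`window_grid()`): seven 2-s, four 3-s and three 4-s windows. In each
window and unit, five temporal statistics are evaluated
(`extract_features()`): mean, sample variance ($n-1$), moment skewness
$m_3/m_2^{3/2}$, excess kurtosis $m_4/m_2^2 - 3$, and the least-squares
slope against time *in seconds* (so slopes read as concentration change
per second). Zero-variance segments take skewness and kurtosis 0 by
convention. Columns are ordered unit → window → statistic, and that
order is the deterministic tie-break everywhere downstream.

The candidate pool can be built at channel level (20 × 14 × 5 = 1400
features) or ROI level (10 × 14 × 5 = 700). The analysis description is
ambiguous about which granularity fed the classifier — the feature-pool
narrative is channel-wise, while the reported optimal feature sets are
ROI-wise. The default here is `"roi"`, which matches the reported
optimal sets, reduces the pool relative to the 20-trial sample size, and
is the level at which the montage was designed; `granularity =
"channel"` reproduces the literal alternative.

## Feature selection and decoding

For a binary contrast (e.g. -90° vs 0° at 58 dB; `contrast_spec()`),
each feature $k$ is scored by the Fisher criterion

$$FS_k = \frac{(\mu_{k,1} - \mu_{k,2})^2}{\sigma^2_{k,1} + \sigma^2_{k,2}},$$

the squared class-mean difference over the summed within-class variances
(`fisher_scores()`). If both class variances vanish the score is
$+\infty$ when the means differ (a perfectly separating feature should
outrank everything) and 0 when they do not.

`loocv_svm()` evaluates feature-set sizes dim = 1…20 with leave-one-out
cross-validation of a linear SVM (cost C = 1 by default; no value is
prescribed, and results are insensitive over a wide range for
standardized features). Critically, *everything trial-dependent — Fisher
ranking and standardization statistics — is recomputed inside each
training fold*. The held-out trial influences nothing about the model
that predicts it; a property test garbles the held-out row and verifies
the training-fold ranking is unchanged. `selection = "global"` provides
the leaky literal alternative (ranking once on all trials) purely as a
comparison baseline — on label-permuted data it inflates accuracy
substantially, which the test suite uses as a regression guard.

With $n = 20$ trials per contrast every LOOCV accuracy is a multiple of
5%, which is exactly the granularity of the published per-subject
accuracy tables shipped in `reference_accuracy_table()`.

**The best-dimension statistic is optimistic.** The reported per-subject
accuracy is the maximum over the 20 candidate dimensions. Under the null
this maximum averages roughly 64% (the per-dimension accuracy itself is
unbiased at ~50%), and its subject-level spread is wide — individual null
subjects can score far above or below chance. This explains why
contrasts with no real signal can sit in the low-to-mid 60s on average,
and why isolated published entries reach implausible extremes (0–5% or
35%). Calibration checks in this package therefore use the unbiased
per-dimension accuracy averaged over dimensions, not the maximum.

### Interhemispheric and sound-level contrasts

The montage is mirror-symmetric, pairing ROIs 1↔6, 2↔7, 3↔8, 4↔9, 5↔10.
For the -90° vs +90° interhemispheric analysis, `pair_hemispheres()`
keeps, per trial, the member of each pair on the requested side relative
to the source — ipsilateral (left hemisphere for -90°, right for +90°)
or contralateral — yielding five units whose features feed the same
decoder. For sound level, `sound_level_decoding()` fixes the location
and decodes 48 vs 58 dB separately per ROI from that ROI's 70 candidate
features.

## Behavioral scoring

Responses are scored in degrees on the speaker arc (speaker $s \mapsto
(s-4)\cdot 30°$). `rms_error()` is $\sqrt{\sum_i e_i^2 / N}$ over the
selected trials. `rms_report()` reports both levels and the pool, which
obey the identity $n\,\mathrm{rms}^2_{all} = n_{low}\mathrm{rms}^2_{low}
+ n_{high}\mathrm{rms}^2_{high}$ exactly. Reports are formatted to two
decimals with halves rounded up (`round_half_up()`), matching the
published tables. Checking the identity against the shipped per-subject
reference RMS table validates every row to within rounding except one
(S22: 7.35 and 10.39 pool to 9.00, not the printed 8.49) — an internal
inconsistency of the published row that the acceptance test asserts
explicitly rather than hiding.

## The synthetic session generator

`simulate_session()` produces a complete session from a seeded config:
a random condition schedule, per-channel oxy-Hb series, and behavioral
responses. Per trial, each channel receives

$$a_{r(\text{ch}),\,\text{loc},\,\text{int}} \cdot g_t \cdot
\big(\mathrm{HRF} * \mathrm{boxcar}_{10s}\big)(t - t_{onset} - \ell),$$

where the HRF is a canonical double-gamma (peak 6 s, undershoot 16 s,
ratio 1/6 — no response model is prescribed by the analysis description,
so the standard one is used), $a$ and $\ell$ are the per-ROI amplitude
and latency of the condition effect, and $g_t \sim N(1, 0.25)$ is a
multiplicative trial gain modeling arousal variability. Noise adds
cardiac (1–1.5 Hz), respiratory (0.2–0.5 Hz) and drift (<0.03 Hz)
sinusoids — frequencies drawn once per session, since these rhythms are
quasi-stationary, with per-channel phases and ±20% amplitude jitter —
plus white measurement noise and a global random-walk component shared
identically across channels (removed exactly by CAR). Behavioral
responses come from a per-location confusion matrix; the
`"lateral_confusion"` preset errs only by reporting ±90° as ±60°, the
characteristic error of normal-hearing listeners.

Default noise amplitudes (mM·mm): cardiac 0.08, respiration 0.05, drift
0.10, white SD 0.03, global 0.10 — chosen once as representative of
band-pass-surviving variability in adult continuous-wave recordings.

The committed `"lateral"` effect preset encodes the phenomenology the
decoding analysis expects: lateral sources drive the contralateral
temporal/parietal ROIs (0.033 mM·mm at peak) harder than the ipsilateral
ones (0.022), front sources evoke moderate bilateral activity (0.015)
with dlPFC engagement (0.026), the -90° response peaks ~1.2 s before the
+90° response, ±30° sources differ from the front by a 0.0015
contralateral tilt only, and sound level has no effect. The amplitudes
were calibrated once so that a 25-subject study lands in the reported
accuracy regimes (lateral contrasts in the 70–80% band with -90/+90
highest; ±30° and sound-level contrasts below the 70% margin) and then
frozen.

**What the generator does not emulate** — and what passing tests
therefore cannot certify about real data: motion artifacts, optode
coupling changes, scalp/superficial blood-flow dynamics beyond a single
global component, condition-dependent behavior-hemodynamics coupling,
inter-subject anatomical variability (all simulated subjects share the
montage and effect map, differing only by seed), and genuine
inter-regional correlation structure beyond the shared global term and
trial gain.

## Problem sizes and runtime choices

Validation runs use, as the package's own choices: 100 null-effect
sessions of 20 trials each (the two contrasted cells at 10 repetitions,
default noise) for decoder calibration; a 5-point amplitude grid with
three common seeds per point for monotonic signal recovery; and a
25-subject study with full 100-trial sessions for the qualitative
range checks, decoding the six location contrasts at 58 dB plus the
per-ROI sound-level contrast at -90°. The two stimulus levels are
statistically identical under the committed preset (no intensity
effect), so decoding one level is representative.

## Known limitations

* Only oxy-Hb is analyzed downstream; deoxy- and total-Hb are produced
  by `mbll_convert()` but no deoxy decoding path is provided.
* No motion-artifact correction or short-separation regression — the
  preprocessing chain assumes seated, still subjects.
* Binary contrasts only; no multiclass decoding across all five
  locations.
* LOOCV with 20 trials has coarse (5%) accuracy resolution and high
  variance; the best-dimension statistic is optimistically biased (see
  above) and should be compared across conditions, not read as an
  absolute information measure.
* The native on-disk format is transparent text; no vendor binary
  formats are parsed.
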