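# nfkbtrace

Single-cell NF-κB nuclear-translocation dynamics from synthetic
two-channel time-lapse movies.

## What this is for

When cells sense lipopolysaccharide (LPS), the transcription factor
NF-κB (p65/RelA) moves from the cytoplasm into the nucleus, and
live-cell imaging of a p65 fluorescent fusion turns that movement into
a per-cell time series. Different LPS preparations elicit markedly
different single-cell dynamics — different peak amplitudes,
times-to-peak, response durations, potency windows, and sensitivity to
blocking of secreted TNF — and quantifying those differences requires a
full image-analysis chain: segment nuclei in a constitutive marker
channel, track them over ~10 hours, normalize nuclear reporter
intensity by each cell's pre-stimulus cytoplasmic level, and reduce
each trace to interpretable statistics.

`nfkbtrace` implements that chain end to end for R users, paired with a
synthetic movie generator that exports ground truth, so every stage is
testable as a parameter-recovery problem: the pipeline must re-measure,
from rendered noisy movies, exactly the population statistics the
generator encoded. It is aimed at people who build or validate
single-cell signaling image-analysis workflows and want a fully
self-contained, deterministic benchmark.

## The quantities

Per cell, the normalized nuclear localization is

    I(t) = mean nuclear reporter intensity at t
           / mean cytoplasmic reporter intensity before stimulation

(background subtracted from both). From each trace the package
computes: an **active** flag (I at least 0.2 above the pre-stimulus
baseline for 3 consecutive frames), **peak amplitude** max I(t),
**time-to-peak**, **peak width** (duration above the level halfway
between post-stimulus minimum and maximum), and a **secondary
activation count**. Populations are compared via the fraction of
active cells against a Hill dose-response p(c) = pmax·c^h/(c^h + K^h),
average active-cell time courses, and cosine distances
1 − u·v/(‖u‖‖v‖) between those averages.

The generator's single-cell model is a gamma-shaped pulse with optional
persistent plateau and delayed secondary bump:

    I(t) = b + A·(t/τ)^s·e^{s(1−t/τ)} + P·(1−e^{−t/τp}) + S(t)

peaking at b + A exactly at t = τ. Three shipped presets (`Sigma`,
`EB`, `UP`) encode measured cross-preparation population statistics
(e.g. EB: 0.49× Sigma's amplitude, 3× its time-to-peak; UP:
1.17× amplitude, 1.45× time-to-peak, with time-to-peak rising from 52
to 129 min as its concentration falls from 5 to 0.05 µg/mL). See the
methods vignette (`vignettes/methods.Rmd`) for the model, presets,
quality control and design rationale.

## Worked example

Simulate one field of 15 cells stimulated with 0.5 µg/mL Sigma LPS,
run the full image-analysis pipeline on the rendered movie, and
summarize the condition:

```r
library(nfkbtrace)

preset <- preparation_preset("Sigma")
cfg <- imaging_config(height = 256, width = 256)   # 120 frames, 5-min cadence
sim <- simulate_condition(preset, conc = 0.5, n_cells = 15, cfg = cfg, seed = 42)

res <- analyze_movie(sim$movie, background = cfg$background)
features <- trace_features_table(res$traces)
head(features[features$active,
              c("id", "peak_amp", "time_to_peak", "peak_width")], 4)
#>   id peak_amp time_to_peak peak_width
#> 1  1 2.115218           65  134.06225
#> 2  2 2.066314           60   45.37801
#> 4  4 1.909785           45   84.11805
#> 6  6 1.994754           80  145.96885

condition_summary(features, res$traces, "Sigma", 0.5)
#> condition_summary: Sigma at 0.5 ug/mL
#>   active 13 / 15 (0.87)
#>   peak_amp 2.042 +- 0.230 | time_to_peak 51.9 +- 17.6 min | width 91.1 +- 30.4 min
```

13 of 15 cells activated (the preset's Hill curve is near-saturated at
this dose); the mean measured peak is about twice the pre-stimulus
cytoplasmic level, reached ~52 min after stimulation — matching the
preset's central amplitude 1.0 above a baseline of 1.0 and central
time-to-peak 47.6 min within this field's sampling noise. Ground truth
for every cell (class, sampled pulse parameters, true trace and
features) is in `sim$truth`.

`run_full(pipeline_config(...), out_dir)` orchestrates whole condition
grids (presets × concentrations × ±sTNFRII × replicate movies) with
TIFF/CSV/JSON artifacts per stage, and `inst/cli/nfkbtrace.R` is a thin
command-line shell over the same functions.

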