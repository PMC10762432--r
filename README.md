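# earbeat

Feasibility analysis of ear-based electrocardiography (ECG): how well do
cardiac rhythms recorded from electrodes on the ear (concha/helix), the
temporal scalp and the lateral neck reproduce the standard Lead I rhythm,
and how does that correspondence improve with ensemble averaging?

The package is aimed at biomedical-signal researchers prototyping wearable
("hearable") ECG pipelines. It provides, end to end:

* a **synthetic data generator**: a heart-vector (equivalent current
  dipole) source `p(t)` built from Gaussian P/Q/R/S/T bumps, rendered
  through per-channel lead vectors into multichannel recordings with
  beat-to-beat RR variability and channel-specific noise (broadband
  EEG/EMG-like background, 50 Hz powerline, baseline wander, EMG bursts);
* an **analytic dipole forward model** (infinite homogeneous medium):
  `phi = p . r / (4 pi sigma |r|^3)`, with lead fields assembled from
  bipolar electrode layouts for wrist-, scalp-, ear-, neck-, and cross-ear
  channels;
* the **processing pipeline**: zero-phase Butterworth filtering (0.5–30 Hz
  for head/ear channels; 0.5–95 Hz plus a 50 Hz notch for the reference),
  Pan–Tompkins R-peak detection on the reference, 600 ms beat windows
  (−200 to +400 ms around R), sliding per-sample **median** rhythms over
  the ensemble grid N = 2, 8, 16, 32, 64, 120, 180, 240, 300, 420, 540
  (n rhythms yield n − N medians), and PQRST peak delineation;
* four **similarity metrics** against the reference grand-median: Pearson
  correlation r (optimum 1), wave amplitude ratio
  war = √(¼ Σ_j ((a_j b_R)/(b_j a_R))²) over j ∈ {P,Q,S,T} (optimum 1),
  wave timing error δwt = √(¼ Σ_j ((c_j−c_R) − (d_j−d_R))²) in ms
  (optimum 0), and normalized variance δnv = RMSE(rhythms vs own
  grand-median)/σ(grand-median) (optimum 0).

## Worked example

Simulate two 3-minute subjects with channel gains wrist:neck:ear:scalp =
1 : 0.2 : 0.1 : 0.05 mV (the 4:2:1 head-channel attenuation ordering) and
the default noise model, run the full pipeline, and average metrics over
subjects:

```r
library(earbeat)

plan <- experiment_plan(n_subjects = 2, duration = 180,
                        n_grid = c(2L, 32L, 120L), seed = 3)
rep <- run_metric_vs_N(plan)
print(rep)
#> <metrics_report> 2 subjects, 4 channels, N grid of 3
#>    channel   N     r  war dwt_ms    dnv
#> 1      ear   2 0.854 3.37 23.818 0.8753
#> 2      ear  32 0.982 1.54  8.013 0.8753
#> 3      ear 120 0.995 1.22  5.517 0.8753
#> 4     neck   2 0.956 1.90 13.727 0.4455
#> 5     neck  32 0.996 1.20  5.455 0.4455
#> 6     neck 120 0.999 1.11  4.165 0.4455
#> 7    scalp   2 0.639 6.29 38.699 1.6879
#> 8    scalp  32 0.943 2.28 11.172 1.6879
#> 9    scalp 120 0.983 1.62  5.558 1.6879
#> 10   wrist   2 0.999 1.02  2.388 0.0508
#> 11   wrist  32 1.000 1.01  1.563 0.0508
#> 12   wrist 120 1.000 1.00  0.654 0.0508
```

Reading the table: the wrist row is the reference compared with itself, so
it sits at the optima apart from residual noise. Single-beat (N = 2) scalp
rhythms correlate poorly with Lead I (r = 0.64) and mistime their waves by
almost 40 ms RMS, but averaging 120 beats recovers r = 0.98 — the
convergence that makes low-amplitude head channels usable. At every N the
metrics order neck > ear > scalp (and δnv the other way), following the
channel gains. `plot_metric_curves(rep)` draws the r/war/δwt-vs-N curves
with a dashed marker at N = 240.

The noiseless volume-conduction benchmark gives the same ordering from
geometry alone (electrode–dipole distance grows neck → ear → scalp):

```r
run_simulation_benchmark(channels = c("wrist", "neck", "ear", "scalp"))
#>   channel    r war dwt_ms r_amplitude_mv
#> 1   wrist 1.00 1.0      0          2.545
#> 2    neck 0.99 1.4      0          0.103
#> 3     ear 0.98 1.5      0          0.057
#> 4   scalp 0.96 1.7      0          0.031
```

Lower-level entry points — `synth_heart_vector()`,
`synth_beat_schedule()`, `render_recording()`, `pan_tompkins()`,
`extract_windows()`, `sliding_medians()`, `grand_median()`,
`delineate()`, `pearson()`, `wave_amplitude_ratio()`,
`wave_timing_error()`, `normalized_variance()` — compose the same pipeline
piecewise; `read_recording()`/`write_recording()` handle CSV and a minimal
WFDB-style format, and `load_config()` resolves YAML/JSON pipeline
configurations. A thin command-line wrapper lives at `inst/cli/earbeat`
(verbs `synth`, `detect`, `simulate`, `run-expa`, `run-expb`). The methods
vignette (`vignettes/ear-ecg-pipeline.Rmd`) documents the models, the
parameter choices and their rationale, and what the synthetic experiments
do and do not demonstrate.

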