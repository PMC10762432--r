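---
title: "Evaluating ear-ECG channels against Lead I: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating ear-ECG channels against Lead I}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(earbeat)
```

## The problem

Hearable devices place electrodes on the concha and helix of the ear, or on
the nearby scalp and neck. The ECG potential available there is orders of
magnitude smaller than at a standard Lead I limb lead, and it is buried in
EEG, temporal-muscle EMG, powerline interference and baseline wander. The
question this package addresses is a feasibility one: after ensemble
averaging over many beats, how closely do the cardiac rhythms recorded at
these head-surface channels match the Lead I rhythm in shape, amplitude
structure and wave timing — and how does that correspondence grow with the
number of beats averaged?

A *cardiac rhythm* here means one beat's PQRST waveform in a 600 ms window
running from 200 ms before to 400 ms after the R maximum, not a heart-rate
pattern. All windows live on this half-open axis `[-200, +400)` ms, so at
500 Hz a rhythm holds exactly 300 samples.

## The source model

The electrical activity of the heart is summarized by a single equivalent
current dipole, the *heart vector* `p(t)`, with components along left-right
(x), front-back (y) and below-above (z). Each channel sees the projection
`l . p(t)` of the heart vector onto its *lead vector* `l`, which encodes
electrode geometry and volume conduction. This linearity is what the whole
pipeline leans on: every channel of a synthetic subject is one lead
projection of one underlying source plus channel-specific noise.

`synth_heart_vector()` builds one cycle of `p(t)` as a sum of five Gaussian
bumps per component — one per P, Q, R, S and T wave. The default
parameterization places the waves at -160, -45, 0, +45 and +220 ms with
widths 20, 12, 15, 12 and 40 ms and Lead-I amplitude ratios of roughly
R:T:P = 10:3:1 with Q and S about -0.3 of R. Those numbers were chosen once,
as plausible Lead-I morphology, under two analytic constraints: the bumps
must overlap so little that the composite peak of each wave stays within
2 ms of its injected centre (peak-interference shift is bounded by the
neighbouring bump's slope divided by the wave's own curvature), and the QRS
spectral width (sd about 10-13 Hz for 12-15 ms bumps) must leave the
amplitude structure essentially untouched by the 0.5-30 Hz head-channel
filter. They are declared synthetic fixture constants, not a reconstruction
of any measured subject.

Two lead-field constructions are provided. `lead_field_from_layout()` is an
analytic dipole model in an infinite homogeneous medium: the potential of a
current dipole is `phi = p . r / (4 pi sigma |r|^3)`, and a bipolar
channel's lead vector is the difference of the point-lead function at its
two terminals. This deliberately replaces tissue-resolved finite-element
modelling; it preserves the qualitative structure that matters at desk
scale — amplitudes fall neck > ear > scalp because the electrode-dipole
distance grows in that order, cross-ear channels exceed single-ear channels
because their terminals span a larger baseline, and all head channels share
a similar projection direction, hence correlate above 0.95 with the
reference — but its absolute millivolt values are not reproduction targets.
`lead_field_gains()` instead sets channel gains directly (default
wrist:neck:ear:scalp = 1:0.2:0.1:0.05 mV of R amplitude, i.e. the 4:2:1
head-channel ratio), which is the controlled configuration used for the
ensemble-size experiments.

## The synthetic recordings

`synth_beat_schedule()` draws RR intervals i.i.d. from a truncated normal
(floor 0.35 s, so consecutive 600 ms windows cannot contain two R maxima).
The default mean RR of 0.85 s gives about 700 beats in a 10-minute
recording, consistent with resting heart rates. No RR autocorrelation,
respiratory modulation or ectopy is modelled: the ensemble-size experiments
only need realistic beat counts and window-level noise, and the median is
insensitive to the fine structure of RR variability.

`render_recording()` tiles the lead-projected cycle at the scheduled beat
times (overlaps sum, as physical superposition requires) and adds
channel-specific noise: broadband Gaussian noise standing in for EEG/EMG
background (default 0.06 mV on head channels), a 50 Hz powerline sinusoid,
slow sinusoidal baseline wander, and Poisson-arriving Hann-windowed EMG
bursts. The wrist reference instead gets low broadband noise (0.01 mV) with
stronger powerline and wander, which its 0.5-95 Hz + notch filter chain
removes. All noise is reproducible bit-for-bit from its seed. Beats that
fall on the output sample grid index the cycle directly (so noiseless
grid-aligned schedules repeat exactly); off-grid beats are rendered by
natural-spline interpolation of the cycle.

What the generator does *not* emulate: electrode-contact drift and motion
artefacts, true EEG spectral structure (the broadband term is white),
subject-specific morphology differences beyond a global amplitude scale,
and pathological rhythms. Passing the test suite therefore demonstrates
that the *pipeline* behaves correctly under controlled conditions with a
known ground truth; it does not certify performance on measured ear-ECG.

## The processing pipeline

`run_algorithm1()` executes the standard chain:

1. Head/ear channels: 0.5-30 Hz third-order Butterworth bandpass.
2. Reference channel: 0.5-95 Hz bandpass plus a second-order IIR notch at
   50 Hz with 5 Hz bandwidth.
3. Pan-Tompkins R-peak detection on the filtered reference only.
4. 600 ms windows around each detected R-peak, in every channel.
5. Sliding median rhythms for each ensemble size N in
   {2, 8, 16, 32, 64, 120, 180, 240, 300, 420, 540}.
6. Four similarity metrics against the reference grand-median.

All filters are applied forward and backward (zero phase). This is a
deliberate choice the processing description leaves open: the timing metric
compares wave latencies across channels filtered with different bandwidths,
and a causal Butterworth's group delay differs between a 0.5-30 Hz and a
0.5-95 Hz design, which would bias wave timings by several milliseconds.
Zero-phase filtering doubles the effective order; edge transients are
contained by mirror-reflection padding (up to 3 s) and by dropping beats
within 1 s of the recording boundaries. Mirror (even) rather than odd
reflection is used because a recording that happens to open mid-QRS has a
boundary sample far from baseline, which odd reflection would turn into a
large DC step. One further documented ambiguity: one description of the
reference bandpass gives a 0.5 Hz lower edge and another gives 1 Hz; the
0.5 Hz reading is adopted throughout.

The Pan-Tompkins implementation follows the classic recipe (5-15 Hz
bandpass, five-point derivative, squaring, 150 ms moving-window
integration, adaptive signal/noise thresholds, 200 ms refractory, T-wave
discrimination inside 360 ms, search-back at 1.66 times the running RR
average) with thresholds initialized from the first 2 s. Because the
integrated waveform lags the R maximum by roughly the integration window,
each accepted detection is refined in two steps: to the largest absolute
value of the 5-15 Hz bandpassed trace within [-200, +50] ms of the
integrator peak, then to the largest absolute value of the filtered
reference within +/-50 ms. Using absolute values makes detection invariant
to polarity inversion (the squaring stage already is). Refinement is on by
default and switchable (`refine = FALSE`).

### Ensembles and the counting convention

For `n` available rhythms and ensemble size `N`, `sliding_medians()`
produces exactly `n - N` median rhythms, median `m` covering beats
`m .. m+N-1` — so 100 consecutive rhythms at N = 2 give 98 medians. This is
the worked arithmetic the pipeline is specified by, and it is adopted
verbatim (rather than the `n - N + 1` count a one-beat slide would more
naturally give). Medians, not means, are used at every N; for even N the
median is the mean of the two central order statistics. The per-sample
sliding median is the one hot loop in the package and is implemented in
C++ (`std::nth_element` per sample and start). The *grand median* is the
per-sample median over all of a channel's rhythms and serves as the
subject-level template.

### Delineation

`delineate()` locates the five wave peaks of a median rhythm with a
fixed-window search: R is the largest absolute extremum in +/-40 ms, which
also fixes the polarity; Q and S are the opposite-polarity extrema within
80 ms before and after R; P is the same-polarity extremum from the window
start to 20 ms before Q; T is the same-polarity extremum from 40 ms after S
to the window end. Ties resolve to the earliest sample; a wave whose search
window is empty is reported missing and propagates as such. These windows
bracket physiological intervals and are configuration-overridable; they are
this package's own re-specification of a peak-extraction step whose
original description is not public, so equivalence with that original is
not claimed.

### The four metrics

With `x` the test rhythm, `y` the reference grand-median, `a`/`b` the test
and reference wave amplitudes and `c`/`d` the timings:

* **Pearson correlation** `r` — shape similarity; optimum 1.
* **Wave amplitude ratio** `war = sqrt((1/4) sum_j ((a_j b_R)/(b_j a_R))^2)`
  over j in {P, Q, S, T} — R-normalized amplitude structure; optimum 1.
  Signs cancel under the square, so inverted channels score identically.
  A printed form of this quantity omits the radical sign; the RMS reading
  is used because it is the only one whose optimum is 1 and it matches the
  quantity's description as an RMS amplitude ratio.
* **Wave timing error**
  `dwt = sqrt((1/4) sum_j ((c_j - c_R) - (d_j - d_R))^2)` in ms — latency
  agreement relative to R; optimum 0.
* **Normalized variance** `dnv = RMSE(windows vs own grand-median) / sd(grand-median)`
  — within-channel beat variability; optimum 0. Squared errors are pooled
  over all rhythms and samples under a single radical (the printed
  single-radical form); per-rhythm pooling is available behind
  `per_rhythm = TRUE` and differs only when noise is heterogeneous across
  beats.

If a wave is missing or its reference amplitude is zero, metrics (ii) and
(iii) average over the remaining waves with the divisor reduced and flag
the result. Within a recording the per-median metrics are averaged; across
subjects the per-channel means are averaged again (`run_metric_vs_N()`).

## Synthetic subjects and problem sizes

A "subject" in `experiment_plan()` is a parameter draw around the
generator defaults: heart rate uniform in 55-85 bpm, one common amplitude
scale in 0.8-1.2 and one noise scale in 0.7-1.3 per subject, each from its
own derived seed. Scaling amplitude and noise globally (not per channel)
keeps gain ratios and noise equality exact within every subject, which is
what makes channel-ordering claims well-posed. The default study
configuration is four channels (wrist reference plus neck, ear, scalp at
4:2:1 gains), 10-minute recordings at 500 Hz, and the full 11-value
ensemble grid; the driving-style variant acquires at 1200 Hz and analyses
at 300 Hz, with downsampling applied before filtering (the other order is
available by resampling after `run_algorithm1` preprocessing if wanted —
both are supported because the processing description does not pin the
order down).

The test suite exercises this at sizes a laptop handles in about a minute:
one full-grid 10-minute subject for the convergence property, five
subjects at N = 240 for the ordering property, 60-120 s fixtures
elsewhere. Under those conditions the scalp channel's mean correlation
rises from about 0.65 at N = 2 to about 0.99 at N = 540, monotonically;
at N = 240 the metrics order r(neck) > r(ear) > r(scalp) and
dwt(neck) < dwt(ear) < dwt(scalp), and the normalized variance grows
scalp-ward — the qualitative structure expected when identical sources
meet channel gains in the ratio 4:2:1 under equal noise.

## Numerical choices and degenerate inputs

* Ensemble sizes exceeding `n - 1` rhythms are skipped with a warning, not
  an error, so short recordings still produce partial reports.
* A zero-variance trace yields an empty peak set; a recording with no
  detected beats is an error.
* Constant rhythms make the Pearson correlation and the normalized
  variance undefined; both raise errors rather than returning NaN.
* Delineation ties break to the earliest sample; beat windows are
  half-open so a cycle is never double-counted at its seam.
* CSV output prints doubles with 17 significant digits, so a write/read
  round trip is bit-exact; the WFDB-style 16-bit writer round-trips to
  within one ADC step (max |x| / 32000 per channel).

## Known limitations

The homogeneous-medium dipole model ignores the strong impedance of the
neck and skull, so its absolute head-surface potentials are optimistic;
only orderings and correlations are meaningful. The noise model is
stationary within a channel, so the normalized variance is nearly
N-independent per channel — real electrode-contact drift would break this.
The delineator extracts peak times only (no onsets/offsets, so no PR/QT
intervals), and the Lead I reference is assumed trustworthy: beats are
never localized from the ear channels themselves.
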