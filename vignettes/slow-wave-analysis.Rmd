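---
title: "Slow-wave detection and characterization on recording grids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Slow-wave detection and characterization on recording grids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wavescan)
```

## The analysis problem

Under deep sleep and anesthesia, the cortex alternates between low-activity
(down) and high-activity (up) states at below 1 Hz. The down-to-up
transitions are not simultaneous across the cortical surface: they sweep
across it as traveling slow waves. Grid recordings — micro-electrode arrays
(ECoG) or wide-field calcium imaging pixels — capture these waves as
systematic per-site delays of the transition times. wavescan turns such
recordings into quantitative wave descriptions in five stages:

1. **Data entry** — a `grid_recording` holds one real-valued time series per
   occupied grid site plus the three pieces of metadata every later stage
   needs: sampling rate (Hz), inter-site spacing (mm), and integer (x, y)
   site coordinates. `check_input()` validates these invariants without
   mutating anything.
2. **Processing** — a user-ordered combination of conditioning blocks
   (detrend, zero-phase 0.1–5 Hz Butterworth band-pass, z-scoring,
   background subtraction, region-of-interest masking, spatial
   downsampling, logMUA estimation). Every block appends its name and full
   parameter set to the recording's history, so each artifact can be traced
   to the exact block sequence that produced it.
3. **Trigger detection** — one of three interchangeable detectors marks the
   down-to-up transition time ("trigger") in each channel.
4. **Wave detection** — triggers are grouped into waves by density-based
   clustering in (x, y, scaled time); optionally the Horn–Schunck optical
   flow of the phase signal and a k-means clustering of waves into
   recurring modes are added.
5. **Characterization** — per-wave and per-(wave, channel) measures:
   velocity, direction, planarity, interwave intervals, wave modes — emitted
   as a tidy table with requested metadata columns replicated into each row.

## The measures

**Velocity.** For one wave, the delay map $T(x,y)$ records when the wave
reached each site, relative to the wave's earliest trigger. The local speed
is

$$v(x,y) = \frac{1}{\sqrt{(\partial_x T)^2 + (\partial_y T)^2}},$$

with derivatives in s/mm. We evaluate the gradient with central finite
differences in the grid interior and one-sided differences at grid edges
and next to missing sites. This stencil makes the formula *exact* for
linear delay maps, i.e. ideal planar waves; the unit tests exploit that.
Sites with zero gradient report `NaN` (undefined), never infinity. Because
near-identical delays between distant sites can produce absurd speeds,
reported velocity distributions are capped at 120 mm/s
(`cap_velocities()`); raw values stay in the table, flagged.

**Direction and planarity.** Channel-wise directions are read from the
optical flow of the phase signal at the time and site of each trigger
(`wave_directions_from_flow()`); a delay-gradient direction
(`grad_direction`, the direction of $+\nabla T$) is also provided, clearly
labeled, for users who prefer a flow-free estimate. The planarity of a wave
with trigger direction vectors $\vec v_i$ is

$$P = \frac{\lVert \sum_i \vec v_i \rVert}{\sum_i \lVert \vec v_i \rVert} \in [0, 1],$$

1 for perfectly aligned (planar) propagation and near 0 for incoherent or
radially symmetric propagation. The bound follows from the triangle
inequality and is verified on random vector sets in the tests.

**Interwave interval.** Per channel, the successive differences of that
channel's wave trigger times.

**Wave modes.** k-means on the trigger-delay matrix (waves × channels,
entries = trigger time − wave onset). The number of modes is a user choice;
there is no universally right `k`. Channels a wave never reached are
imputed with that wave's maximum delay — a channel the wave did not reach
is "late" — with mean-imputation available. Mode ids are ordered by cluster
size. When fewer distinct delay patterns than `k` exist, the operation
still terminates, assigns a single mode, and reports a between-cluster
separation of 0 (the raw k-means ratio would be floating-point residue).

**Effect size.** Comparisons between measure distributions use the pooled
standard-deviation effect size
$ES = |\langle A\rangle - \langle B\rangle| / \sigma_{pooled}$ with
$\sigma_{pooled}^2 = ((N_A{-}1)\sigma_A^2 + (N_B{-}1)\sigma_B^2)/(N_A{+}N_B{-}2)$,
and density summaries use a Gaussian KDE with Scott's-rule bandwidth
($\hat\sigma\, n^{-1/5}$), except interwave intervals, which use
$0.2\,\hat\sigma$ as the kernel size (their distributions are wide and
multi-modal, and Scott's rule over-smooths them).

## Trigger detectors and their assumptions

* **Threshold** (`detect_threshold_triggers()`): for signals with sharp,
  well-separated states — typically logMUA — the amplitude distribution is
  bimodal. The channel threshold is the central minimum of a two-Gaussian
  fit (EM, k-means-initialized means, equal starting weights; the fit
  declares "no bimodal structure" when the component means are closer than
  the sum of their standard deviations). A left-peak variant fits only the
  down-state mode, estimating its spread from the samples left of the first
  dominant density peak, and sets the threshold at
  `mean + sd * SIGMA_FACTOR`; it doubles as the automatic fallback when
  the two-Gaussian fit fails on a channel. Crossings are interpolated
  linearly between samples, and a paired duration filter
  (`filter_min_state_durations()`) removes implausibly short states while
  preserving up/down alternation.
* **Hilbert phase** (`detect_hilbert_triggers()`): for slow, smooth signals
  (calcium indicators) the analytic-signal phase is a robust clock. Our
  convention puts phase 0 at the signal peak, so −π/2 sits on the rising
  flank; a trigger is an upward crossing of −π/2 that is followed by a
  phase-0 peak before the next crossing. The signal must be detrended and
  z-scored first — offset or drift corrupts the phase.
* **Minima** (`detect_minima_triggers()`): the onset of a transient is the
  local minimum preceding a dominant peak, refined by three rules: peaks
  must exceed a relative threshold inside a moving window; peaks must be
  separated by a minimum distance (higher peaks take precedence when they
  collide); and the minimum must be followed by a strictly rising signal
  for a set interval. When several minima fall between two accepted peaks,
  the last one before the later peak is used. Minima are non-strict on the
  left (a flat baseline running into a rise counts), so the very first
  transient of a noiseless recording is not missed. Minima are reported at
  sample resolution; the two phase-based detectors interpolate and so agree
  with the minima detector up to a constant offset, which the tests assert
  as constancy rather than equality. The moving-window length has no
  natural default and is a required parameter.

## logMUA estimation

Broadband electrode signals are converted to a log multi-unit activity
estimate: a moving window (default 0.3 s) samples the recording at
`mua_rate` (default 100 Hz); within each window a Welch PSD is computed
with `nperseg = round(sampling_rate / f_low)` samples per segment (the
shortest segment that resolves the 200 Hz band edge), 50% overlap (floored),
Hann window, and per-segment linear detrending; the MUA is the mean power
in the 200–1500 Hz band divided by the mean full-spectrum power, and the
output is its natural log. The log base is a free choice — it shifts and
scales the bimodal distribution without moving the threshold fit — and e is
used. Windows are centered on output sample times; edge windows are
truncated rather than zero-padded, and their count is recorded in the
history. A window spanning the full spectrum gives logMUA ≈ 0 by
construction, which the tests use as a null check.

## The synthetic generator as study design

Every stage is validated against `simulate_wave_recording()` (calcium-like:
causal difference-of-exponentials kernel, default rise 0.1 s and decay
0.5 s, the order of GCaMP6f dynamics) and `simulate_mua_recording()`
(MUA-like), both with exact per-channel, per-wave trigger ground truth.
Planar waves delay site $(x,y)$ by its projection on the propagation
direction divided by $v_0$; radial waves by distance from the origin over
$v_0$. Radial waves double as the "complex, low-planarity" fixture: on a
symmetric grid their flow vectors cancel and $P$ is near 0. Noise is
Gaussian and white; pink noise is deferred.

The MUA generator deserves a note. A state-dependent gain applied uniformly
to white noise cannot modulate the logMUA, because the in-band/full-spectrum
ratio is invariant under rescaling. Real recordings escape this because
unmodulated power coexists with the modulated spiking band (and the slow
LFP itself is invisible to 5 ms Welch segments after linear detrending).
The generator therefore emits band-limited (200–1500 Hz) noise whose
standard deviation is multiplied by `up_gain` during up states, plus an
unmodulated white noise floor (`floor_sd`, default 0.45, about 20% of the
band power). With `up_gain = 5` this yields an up/down variance ratio of
about 21 and a cleanly bimodal logMUA on which the threshold detector
recovers the exact up-state count.

**Geometry of the parameter-recovery study.** Trigger times carry a jitter
set by the noise level and the signal's rise, about 3–5 ms at the study's
noise settings, independent of grid pitch. Whether Eq.-1 velocities are
recoverable therefore depends on the ratio of per-site delays to that
jitter: at an imaging-like 0.05 mm pitch a 30 mm/s wave crosses a site in
1.7 ms — below the jitter floor, so channel-wise speeds are biased low *by
construction*, for any estimator. The recovery study accordingly uses an
electrode-array-like geometry (12×12 sites, 0.5 mm pitch, 50 Hz, waves
every 6 s), where per-site delays (17–100 ms for 5–30 mm/s) dominate the
jitter. Under those conditions the pipeline recovers median channel
velocities within a few percent of truth, circular-mean directions within
about 1.5°, and planarity ≥ 0.99 for planar waves, across five seeds per
condition. This is the package's own study-design choice; users analyzing
fine-pitch imaging data should expect (and will see) the low-speed bias for
fast waves, which is exactly why the delay-resolution question matters in
practice.

What the generator does *not* emulate: spatially correlated (pink) noise,
hemodynamic or photobleaching drifts, indicator nonlinearity, spiral or
colliding waves, and non-stationary wave statistics. Passing tests on
synthetic data therefore validate the algorithmic contracts, not robustness
to every artifact of real recordings.

## Wave clustering parameters

Clustering operates in (x, y, t·`TIME_SPACE_RATIO`) with
`TIME_SPACE_RATIO = v0 / (sampling_rate × spatial_scale)` grid units per
frame — the scaling under which a wave at the reference speed $v_0$ is
isotropic. On a 25 Hz / 0.05 mm imaging grid, the expected 10–20 mm/s maps
to ratios 8–16; doubling $v_0$ doubles the ratio exactly. The density
parameters default to `NEIGHBOUR_DISTANCE = 4` grid units and
`MIN_SAMPLES_PER_WAVE = 10`; they were calibrated on the synthetic fixtures
(recall of true wave membership ≥ 0.99 across seeds at both tested
geometries) and should be recalibrated for data with very different trigger
densities. Within one cluster a channel may fire twice; delay maps need one
value per site, so the default policy keeps each channel's earliest trigger
(`dedupe_channel_triggers()`), configurable to keep all.

## Optical flow: numerical choices

The Horn–Schunck functional (brightness constancy plus α²-weighted
smoothness, both quadratic) is minimized by the classical Jacobi iteration
with a 3×3 Scharr derivative filter; α defaults to 1.5, weighting
smoothness against constancy. Phase input is differentiated through the
unit phasor $z = e^{i\varphi}$ ($\varphi_x = \mathrm{Im}(\bar z\, z_x)$,
$E_t = \arg(z_{t+1}\bar z_t)$), which is the wrapped angular difference in
(−π, π]: correct across the ±π seam and exactly invariant to adding 2π to
the field. Iteration stops when the mean-square update falls below 1e-6 or
at 500 iterations (a warning flags non-convergence in the returned
parameters). The converged field is smoothed with a Gaussian kernel, default
σ = 1 site in space and 1 frame in time, reflecting the expected scale of
wave activity; both are exposed. Missing sites are NaN; derivative stencils
touching a NaN propagate it, so flow is undefined at and immediately around
masked sites, and boundary derivatives use edge replication (which biases
speed, not direction, near edges — directions are accurate to a few degrees
on interior sites, speeds to roughly 10–15%). Flow is computed on the full
recording by default rather than per-wave windows, matching its definition
as a continuous vector-valued signal; per-wave windows can be had by
slicing the recording first. The flow field is persisted alongside wave
output by the orchestrator by default.

## Pipeline orchestration and configuration

`run_pipeline()` executes the configured stages in order, natively (no
external workflow engine), writing per-stage outputs, a JSON log of block
sequence, parameters, package version and elapsed time, and optional QC
plots; a failing block halts the run naming the stage, block, and offending
parameters, while a failing *plot* only warns. Outputs newer than their
configs are reused on rerun. Configuration is YAML, one file set per stage,
with hierarchical profiles: lookup tries the full profile name, then strips
underscore-separated subcategories one at a time, keeping any '|'-variation
suffix through the loop; only when the bare variation file is absent is the
variation dropped and the stripping restarted, ending at `config.yaml`.
Since '|' is awkward in file names, `@` is accepted as an equivalent
spelling. A top-level `pipeline.yaml` lists the stages and global
parameters that override identically named stage parameters (e.g. one seed
or plot format for all stages). The wave-wise and channel-wise
characterizations are two variants selectable per run rather than one
merged stage.

## Open design choices made here

* Welch `nperseg` uses round-to-nearest of `sampling_rate / f_low` (no
  rounding rule is canonical).
* The "normalize" step applied to broadband electrode data before logMUA is
  implemented as z-scoring.
* Wave-wise velocity is the mean of that wave's capped channel velocities;
  a global plane-fit velocity (`velocity_plane_fit`) is included as the
  alternative since neither definition is canonical. Direction histograms
  weight per trigger, not per wave.
* Histogram binning for threshold fits follows the default density
  bandwidth (Freedman–Diaconis-like behavior); configurable.
* Spatial downsampling reduces k×k blocks by their mean, matching the
  physics of sensor integration at coarser pitch.

## Problem sizes

The shipped tests and reference computations run on grids of 6×6 to 20×20
sites, 3–6 waves per recording, and five seeds per stochastic condition —
sizes chosen so the full suite completes in a few minutes while every
stochastic claim still averages over seeds. All reported numbers in the
README are produced by the code at these sizes.

## Known limitations

* Channel-wise velocity is biased low when per-site delays approach the
  trigger-jitter floor (see the geometry note above); the bias is a
  property of delay-map differentiation, not of a particular detector.
* DBSCAN region queries are exact but brute-force (O(n²) in the trigger
  count); fine for 10⁴ triggers, slow beyond.
* The orchestrator's cache keys on file modification times, not content
  hashes.
* Critical-point analysis of the flow field (sources, sinks, spirals) and
  anatomical registration are out of scope.
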