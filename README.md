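# wavescan

Detection and characterization of propagating cortical slow waves on
recording grids.

During deep sleep and anesthesia, cortical activity alternates between
low-activity (down) and high-activity (up) states below 1 Hz, and the
down-to-up transitions travel across the cortex as slow waves. Electrode
arrays (ECoG) and wide-field calcium imaging both capture these waves as
per-site delays of the transition times — but at very different temporal
and spatial resolutions, which makes quantitative comparison across
techniques hard. wavescan is a modular five-stage pipeline for exactly
that: it conditions grid recordings, detects per-channel up-state
transition triggers, groups triggers into waves, and computes comparable
wave measures — velocity, direction, planarity, interwave intervals, wave
modes — for either data type. It is aimed at systems neuroscientists
analyzing slow-wave (and more generally, traveling-wave) dynamics on
rectangular sensor grids.

## The measures at the core

For one wave, the delay map `T(x, y)` gives the arrival time at each grid
site relative to the wave's onset. The channel-wise speed is

    v(x, y) = 1 / sqrt( (dT/dx)^2 + (dT/dy)^2 )        [mm/s]

with gradients taken by central finite differences (exact for planar
waves). Channel-wise directions come from the Horn–Schunck optical flow of
the signal's Hilbert phase, evaluated at each trigger's site and time, and
the alignment of a wave's direction vectors v_i is its planarity

    P = || sum_i v_i || / sum_i || v_i ||   in [0, 1]

(1 = planar, ~0 = incoherent or radial). Triggers are grouped into waves by
density clustering (DBSCAN semantics) in `(x, y, t * r)` with the
time-to-space scaling `r = v0 / (sampling_rate * spatial_scale)` grid units
per frame. Three interchangeable trigger detectors cover the two data
regimes: amplitude thresholding with a two-Gaussian fit (for logMUA
signals, themselves computed here as the log ratio of 200–1500 Hz Welch
power to full-spectrum power), Hilbert-phase crossing of −π/2, and refined
local minima. A synthetic-data generator with exact ground truth makes
every stage testable end to end.

## Worked example

Simulate three planar waves (15 mm/s, 45°) on a 12×12 grid at 0.5 mm pitch
and 50 Hz, then run the full chain:

```r
library(wavescan)

sim <- simulate_wave_recording(n_x = 12, n_y = 12, spatial_scale = 0.5,
                               sampling_rate = 50, n_waves = 3, period = 6,
                               v0 = 15, theta = pi / 4, noise_sd = 0.05,
                               seed = 1)

proc <- sim$recording |> detrend() |> band_pass_filter(0.1, 5) |> zscore()
ts   <- detect_hilbert_triggers(proc)
r    <- compute_time_space_ratio(15, 50, 0.5)   # 0.6 grid units / frame
ws   <- cluster_triggers_to_waves(ts, r) |> dedupe_channel_triggers()
flow <- compute_optical_flow(phase_field(proc))
ws   <- wave_directions_from_flow(ws, flow)
emit_table(ws, "wave_wise")
```

```
# A tibble: 3 × 8
   wave n_channels onset velocity velocity_plane_fit direction planarity  mode
  <int>      <int> <dbl>    <dbl>              <dbl>     <dbl>     <dbl> <int>
1     1        144  1.01     15.3               15.2     0.791     0.999    NA
2     2        144  7.00     15.0               15.0     0.782     0.999    NA
3     3        144 13.0      15.2               15.0     0.788     0.999    NA
```

All three simulated waves are recovered on all 144 channels. The mean
channel-wise velocities (15.0–15.3 mm/s) sit within 2% of the simulated
15 mm/s; the circular-mean flow directions (0.78–0.79 rad) match the
simulated π/4 ≈ 0.785 within half a degree; and planarity ≈ 1 identifies
the waves as planar. `emit_table(ws, "channel_wise")` gives the same
measures per (wave, channel), including per-channel interwave intervals.
`autoplot()` methods provide QC figures for every intermediate object, and
`run_pipeline()` drives the whole chain from YAML configs with profile
support and provenance logs. A command-line front end is included at
`inst/cli/wavescan.R`.

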