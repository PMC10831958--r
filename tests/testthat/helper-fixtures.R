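# Fixture builders shared across the suite. Everything is generated in code;
# sizes are kept small so each file runs in seconds.

# a well-formed grid recording with arbitrary signals
make_rec <- function(n_x = 4, n_y = 4, n_t = 100, fs = 25, scale = 0.05,
                     fill = function(n) stats::rnorm(n)) {
  coords <- expand.grid(x = 0:(n_x - 1), y = 0:(n_y - 1))
  grid_recording(matrix(fill(n_x * n_y * n_t), nrow = n_x * n_y),
                 coords, fs, scale)
}

# recording where every channel carries the same 1D signal
signal_rec <- function(s, n_ch = 4, fs = 25, scale = 0.05) {
  coords <- expand.grid(x = 0:(n_ch - 1), y = 0L)
  grid_recording(matrix(rep(s, each = n_ch), nrow = n_ch), coords, fs, scale)
}

# standard imaging-style processing chain used ahead of phase-based detectors
process_calcium <- function(rec) {
  rec |> detrend() |> band_pass_filter(0.1, 5) |> zscore()
}

# the parameter-recovery study geometry: electrode-like pitch so that
# per-site delays are resolvable against trigger-time jitter
recovery_sim <- function(v0, theta, seed, pattern = "planar", n = 12) {
  simulate_wave_recording(
    n_x = n, n_y = n, spatial_scale = 0.5, sampling_rate = 50,
    n_waves = 3, period = 6, v0 = v0, theta = theta, pattern = pattern,
    noise_sd = 0.05, seed = seed
  )
}

# full planar-recovery chain: returns channel-wise measures table
recover_measures <- function(v0, theta, seed, pattern = "planar", n = 12) {
  sim <- recovery_sim(v0, theta, seed, pattern, n)
  proc <- process_calcium(sim$recording)
  ts <- detect_hilbert_triggers(proc)
  ratio <- compute_time_space_ratio(v0, proc$sampling_rate, proc$spatial_scale)
  ws <- cluster_triggers_to_waves(ts, ratio, neighbour_distance = 3,
                                  min_samples_per_wave = 10) |>
    dedupe_channel_triggers()
  flow <- compute_optical_flow(phase_field(proc))
  ws <- wave_directions_from_flow(ws, flow)
  emit_table(ws, "channel_wise")
}

circ_mean_test <- function(theta) atan2(mean(sin(theta)), mean(cos(theta)))

ang_diff <- function(a, b) abs(atan2(sin(a - b), cos(a - b)))
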