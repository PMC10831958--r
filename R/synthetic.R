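#' Ground-truth trigger times for synthetic waves
#'
#' For a planar wave the true arrival time at grid site (x, y) is
#' `onset + (x cos(theta) + y sin(theta)) * spatial_scale / v0`; for a
#' radial wave it is `onset + ||site - origin|| / v0`, distances in mm.
#' Sites "behind" a planar wavefront (negative projected delay) are shifted
#' so that the earliest site of each wave defines its onset.
#'
#' @param waves tibble with one row per wave: columns `wave`, `pattern`
#'   (`"planar"` or `"radial"`), `v0` (mm/s), `theta` (rad; planar),
#'   `origin_x`, `origin_y` (mm; radial), `onset` (s).
#' @param coords tibble of integer grid coordinates `x`, `y`.
#' @param spatial_scale inter-site spacing, mm.
#' @return tibble with columns `wave`, `channel`, `x`, `y`, `time` — the true
#'   trigger time of every wave at every site.
#' @export
wave_ground_truth <- function(waves, coords, spatial_scale) {
  purrr::pmap_dfr(waves, function(wave, pattern, v0, theta, origin_x, origin_y, onset, ...) {
    if (pattern == "planar") {
      delay <- (coords$x * cos(theta) + coords$y * sin(theta)) * spatial_scale / v0
      delay <- delay - min(delay)
    } else {
      dx <- coords$x * spatial_scale - origin_x
      dy <- coords$y * spatial_scale - origin_y
      delay <- sqrt(dx^2 + dy^2) / v0
      delay <- delay - min(delay)
    }
    tibble::tibble(
      wave = wave, channel = seq_len(nrow(coords)),
      x = coords$x, y = coords$y, time = onset + delay
    )
  })
}

#' Calcium-like response kernel
#'
#' Causal difference-of-exponentials `A (exp(-t/tau_decay) - exp(-t/tau_rise))`
#' for `t >= 0`, scaled so its maximum equals `amplitude`. Defaults emulate
#' the rise/decay of GCaMP6f-order indicator dynamics. The kernel peaks
#' `peak_lag` seconds after its onset (returned as an attribute so detectors
#' referenced to the peak can compensate).
#'
#' @param t times in seconds (relative to kernel onset).
#' @param tau_rise,tau_decay rise and decay time constants, s.
#' @param amplitude peak amplitude.
#' @return kernel values at `t`; attribute `"peak_lag"` (s).
#' @export
calcium_kernel <- function(t, tau_rise = 0.1, tau_decay = 0.5, amplitude = 1) {
  stopifnot(tau_decay > tau_rise, tau_rise > 0)
  peak_lag <- tau_rise * tau_decay / (tau_decay - tau_rise) * log(tau_decay / tau_rise)
  peak_val <- exp(-peak_lag / tau_decay) - exp(-peak_lag / tau_rise)
  out <- ifelse(t >= 0, (exp(-t / tau_decay) - exp(-t / tau_rise)) / peak_val, 0) * amplitude
  attr(out, "peak_lag") <- peak_lag
  out
}

make_wave_table <- function(n_waves, period, pattern, v0, theta,
                            origin, t_first, n_x, n_y, spatial_scale) {
  if (is.null(origin)) {
    origin <- c((n_x - 1) / 2, (n_y - 1) / 2) * spatial_scale
  }
  tibble::tibble(
    wave = seq_len(n_waves),
    pattern = rep_len(pattern, n_waves),
    v0 = rep_len(v0, n_waves),
    theta = rep_len(theta, n_waves),
    origin_x = origin[1], origin_y = origin[2],
    onset = t_first + (seq_len(n_waves) - 1) * period
  )
}

#' Simulate a calcium-like grid recording with known waves
#'
#' Each channel's signal is the sum over waves of a causal response kernel
#' placed at that channel's true trigger time, plus i.i.d. Gaussian noise.
#' The ground truth (per-wave, per-channel trigger times) is returned with
#' the recording, so downstream detection and characterization can be tested
#' without real data.
#'
#' @param n_x,n_y grid dimensions (sites).
#' @param spatial_scale inter-site spacing, mm. Default 0.05 (wide-field
#'   imaging pixel pitch).
#' @param sampling_rate Hz. Default 25 (imaging frame rate).
#' @param n_waves number of waves.
#' @param period onset-to-onset spacing of consecutive waves, s.
#' @param pattern `"planar"`, `"radial"`, or a vector (recycled per wave).
#' @param v0 propagation speed, mm/s (recycled per wave).
#' @param theta planar propagation direction, rad (recycled per wave).
#' @param origin radial origin in mm `c(x, y)`; default grid center.
#' @param tau_rise,tau_decay,amplitude kernel parameters, see [calcium_kernel()].
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param t_first onset of the first wave, s.
#' @param padding extra recording time after the last transient, s.
#' @param seed RNG seed (mandatory: same seed, bit-identical output).
#' @return list with elements `recording` (a [grid_recording()]) and `truth`
#'   (ground-truth tibble, one row per wave x channel; wave parameters in
#'   `attr(truth, "waves")`, kernel peak lag in `attr(truth, "peak_lag")`).
#' @examples
#' sim <- simulate_wave_recording(n_x = 8, n_y = 8, n_waves = 2, seed = 1)
#' sim$recording
#' head(sim$truth)
#' @export
simulate_wave_recording <- function(n_x = 20, n_y = 20, spatial_scale = 0.05,
                                    sampling_rate = 25, n_waves = 5, period = 4,
                                    pattern = "planar", v0 = 15, theta = 0,
                                    origin = NULL,
                                    tau_rise = 0.1, tau_decay = 0.5,
                                    amplitude = 1, noise_sd = 0.05,
                                    t_first = 1, padding = 1, seed) {
  if (missing(seed)) stop("seed is mandatory")
  coords <- tidyr::expand_grid(y = 0:(n_y - 1), x = 0:(n_x - 1))[, c("x", "y")]
  waves <- make_wave_table(n_waves, period, pattern, v0, theta, origin,
                           t_first, n_x, n_y, spatial_scale)
  truth <- wave_ground_truth(waves, coords, spatial_scale)
  support <- 5 * tau_decay
  max_cross <- max(truth$time - waves$onset[truth$wave])
  if (n_waves > 1 && period < support + max_cross) {
    stop("waves overlap within the kernel support; increase period")
  }
  duration <- max(truth$time) + support + padding
  n_t <- ceiling(duration * sampling_rate)
  tt <- (seq_len(n_t) - 1) / sampling_rate
  set.seed(seed)
  signals <- matrix(stats::rnorm(nrow(coords) * n_t, sd = noise_sd),
                    nrow = nrow(coords))
  peak_lag <- NA_real_
  for (i in seq_len(nrow(truth))) {
    k <- calcium_kernel(tt - truth$time[i], tau_rise, tau_decay, amplitude)
    peak_lag <- attr(k, "peak_lag")
    signals[truth$channel[i], ] <- signals[truth$channel[i], ] + as.numeric(k)
  }
  rec <- grid_recording(signals, coords, sampling_rate, spatial_scale,
                        units = "dF/F",
                        annotations = list(source = "synthetic", kind = "calcium_like"))
  rec <- append_history(rec, "simulate_wave_recording",
                        list(n_waves = n_waves, v0 = v0, theta = theta,
                             pattern = pattern, noise_sd = noise_sd, seed = seed))
  attr(truth, "waves") <- waves
  attr(truth, "peak_lag") <- peak_lag
  list(recording = rec, truth = truth)
}

#' Simulate a MUA-like broadband recording with known up states
#'
#' Emulates high-sampling-rate extracellular recordings whose high-frequency
#' power is amplitude-modulated by up/down states: each channel is
#' band-limited (`band`) Gaussian noise — the population-spiking component —
#' whose standard deviation is multiplied by `up_gain` inside up-state
#' windows `[trigger, trigger + d_up]`, superposed on an unmodulated
#' broadband noise floor. The state-independent floor is what makes the
#' relative in-band spectral power (logMUA) state-dependent; without it the
#' in-band/full-spectrum ratio would be invariant under the up-state gain.
#' Triggers follow the same propagating-wave ground truth as
#' [simulate_wave_recording()].
#'
#' @inheritParams simulate_wave_recording
#' @param sampling_rate Hz; must exceed twice `band[2]`.
#' @param d_up up-state duration, s.
#' @param band frequency band of the modulated spiking component, Hz;
#'   `band[2]` must be below Nyquist.
#' @param up_gain spiking-noise amplitude multiplier during up states; 1
#'   gives a statistically stationary signal with no detectable states.
#' @param band_sd down-state standard deviation of the band-limited
#'   component.
#' @param floor_sd standard deviation of the unmodulated white noise floor.
#' @return list with `recording` and `truth` as in [simulate_wave_recording()];
#'   `truth` additionally carries `attr(truth, "d_up")`.
#' @export
simulate_mua_recording <- function(n_x = 8, n_y = 8, spatial_scale = 0.55,
                                   sampling_rate = 5000, n_waves = 4, period = 2,
                                   pattern = "planar", v0 = 30, theta = 0,
                                   origin = NULL, d_up = 0.5,
                                   band = c(200, 1500), up_gain = 5,
                                   band_sd = 1, floor_sd = 0.45,
                                   t_first = 0.5, padding = 0.5, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (band[2] >= sampling_rate / 2) stop("band_high must be below Nyquist")
  coords <- tidyr::expand_grid(y = 0:(n_y - 1), x = 0:(n_x - 1))[, c("x", "y")]
  waves <- make_wave_table(n_waves, period, pattern, v0, theta, origin,
                           t_first, n_x, n_y, spatial_scale)
  truth <- wave_ground_truth(waves, coords, spatial_scale)
  max_cross <- max(truth$time - waves$onset[truth$wave])
  if (n_waves > 1 && period < d_up + max_cross) {
    stop("up states overlap; increase period or shorten d_up")
  }
  duration <- max(truth$time) + d_up + padding
  n_t <- ceiling(duration * sampling_rate)
  tt <- (seq_len(n_t) - 1) / sampling_rate
  set.seed(seed)
  bf <- signal::butter(4, band / (sampling_rate / 2), type = "pass")
  spiking <- matrix(stats::rnorm(nrow(coords) * n_t), nrow = nrow(coords))
  spiking <- t(apply(spiking, 1L, function(s) {
    f <- signal::filtfilt(bf, s)
    f / stats::sd(f) * band_sd
  }))
  gain <- matrix(1, nrow(coords), n_t)
  for (i in seq_len(nrow(truth))) {
    idx <- tt >= truth$time[i] & tt < truth$time[i] + d_up
    gain[truth$channel[i], idx] <- up_gain
  }
  signals <- spiking * gain +
    matrix(stats::rnorm(nrow(coords) * n_t, sd = floor_sd), nrow = nrow(coords))
  rec <- grid_recording(signals, coords, sampling_rate, spatial_scale,
                        units = "uV",
                        annotations = list(source = "synthetic", kind = "mua_like"))
  rec <- append_history(rec, "simulate_mua_recording",
                        list(n_waves = n_waves, v0 = v0, up_gain = up_gain,
                             d_up = d_up, seed = seed))
  attr(truth, "waves") <- waves
  attr(truth, "d_up") <- d_up
  list(recording = rec, truth = truth)
}
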