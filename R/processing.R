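#' Signal-conditioning blocks (stage 2)
#'
#' These blocks form the processing stage: any subset may be chosen and
#' ordered freely ("choose any"), and each appends one record to the
#' recording's processing history. Typical chains are
#' `roi -> background -> detrend -> band-pass -> z-score` for imaging data
#' and `background -> detrend -> normalize -> logMUA -> z-score` for
#' broadband electrode data.
#'
#' @name processing
NULL

#' Remove per-channel offset or linear trend
#'
#' @param rec a [grid_recording()].
#' @param order 0 subtracts the channel mean; 1 subtracts the least-squares
#'   linear fit.
#' @return the detrended recording.
#' @export
detrend <- function(rec, order = 1) {
  stopifnot(order %in% c(0, 1))
  n <- n_samples(rec)
  if (order == 0) {
    rec$signals <- rec$signals - rowMeans(rec$signals)
  } else {
    t0 <- seq_len(n) - (n + 1) / 2          # centered regressor
    denom <- sum(t0^2)
    slope <- (rec$signals %*% t0) / denom
    rec$signals <- rec$signals - rowMeans(rec$signals) -
      tcrossprod(as.numeric(slope), t0)
  }
  append_history(rec, "detrend", list(order = order))
}

#' Zero-phase Butterworth band-pass filter
#'
#' Second-order (by default) Butterworth band-pass applied forward and
#' backward per channel, so the passband is phase-neutral — required for the
#' phase-based trigger detectors downstream. The canonical slow-wave band is
#' 0.1–5 Hz.
#'
#' @param rec a [grid_recording()].
#' @param f_low,f_high band edges in Hz, `0 < f_low < f_high < ` Nyquist.
#' @param order filter order.
#' @return the filtered recording.
#' @export
band_pass_filter <- function(rec, f_low = 0.1, f_high = 5, order = 2) {
  nyq <- rec$sampling_rate / 2
  if (!(f_low > 0 && f_low < f_high && f_high < nyq)) {
    stop("invalid band: need 0 < f_low < f_high < Nyquist (", nyq, " Hz)")
  }
  bf <- signal::butter(order, c(f_low, f_high) / nyq, type = "pass")
  rec$signals <- t(apply(rec$signals, 1L, function(s) signal::filtfilt(bf, s)))
  append_history(rec, "band_pass_filter",
                 list(f_low = f_low, f_high = f_high, order = order))
}

#' Z-score each channel
#'
#' Channels with zero variance cannot be standardized; they are set to NaN
#' with a warning rather than aborting the run.
#'
#' @param rec a [grid_recording()].
#' @return the standardized recording (per channel mean 0, sd 1).
#' @export
zscore <- function(rec) {
  mu <- rowMeans(rec$signals)
  sdv <- apply(rec$signals, 1L, stats::sd)
  flat <- sdv == 0 | !is.finite(sdv)
  if (any(flat)) {
    warning(sum(flat), " zero-variance channel(s) set to NaN")
    sdv[flat] <- NA_real_
  }
  rec$signals <- (rec$signals - mu) / sdv
  rec$units <- "z"
  append_history(rec, "zscore", list(n_flat = sum(flat)))
}

#' Subtract a per-site background
#'
#' @param rec a [grid_recording()].
#' @param mode `"temporal_mean"` (each channel's own time average) or
#'   `"provided_frame"`.
#' @param frame numeric vector of per-channel background values (required for
#'   `"provided_frame"`; length `n_channels`).
#' @return the background-subtracted recording.
#' @export
subtract_background <- function(rec, mode = c("temporal_mean", "provided_frame"),
                                frame = NULL) {
  mode <- match.arg(mode)
  bg <- switch(mode,
    temporal_mean = rowMeans(rec$signals),
    provided_frame = {
      if (is.null(frame) || length(frame) != n_channels(rec)) {
        stop("frame must have one value per channel")
      }
      as.numeric(frame)
    }
  )
  rec$signals <- rec$signals - bg
  append_history(rec, "subtract_background", list(mode = mode))
}

#' Restrict analysis to a region of interest
#'
#' Channels outside the mask are marked empty via the channel mask; they are
#' never renumbered or dropped, so grid geometry is preserved.
#'
#' @param rec a [grid_recording()].
#' @param mask logical vector over channels (`TRUE` = keep).
#' @return the recording with an updated channel mask.
#' @export
roi_selection <- function(rec, mask) {
  mask <- as.logical(mask)
  stopifnot(length(mask) == n_channels(rec))
  if (!any(mask)) stop("ROI mask selects no channels")
  rec$channel_mask <- rec$channel_mask & mask
  append_history(rec, "roi_selection", list(n_active = sum(rec$channel_mask)))
}

#' Spatially downsample the grid
#'
#' Averages non-overlapping `k x k` blocks of sites (ignoring empty sites),
#' emulating a sensor with `k`-fold coarser pitch: the inter-site spacing is
#' multiplied by `k` and grid dimensions become `ceiling(n / k)`.
#'
#' @param rec a [grid_recording()].
#' @param k integer downsampling factor, `>= 1`.
#' @return the downsampled recording.
#' @export
spatial_downsample <- function(rec, k) {
  k <- as.integer(k)
  stopifnot(k >= 1L)
  if (k == 1L) return(append_history(rec, "spatial_downsample", list(k = 1L)))
  d <- grid_dims(rec)
  if (k > max(d)) stop("k exceeds both grid dimensions")
  block <- rec$coords$x %/% k + (rec$coords$y %/% k) * ceiling(d[1] / k)
  keep <- rec$channel_mask
  blocks <- sort(unique(block[keep]))
  sig <- t(vapply(blocks, function(b) {
    rows <- which(block == b & keep)
    colMeans(rec$signals[rows, , drop = FALSE], na.rm = TRUE)
  }, numeric(n_samples(rec))))
  coords <- tibble::tibble(
    x = blocks %% ceiling(d[1] / k),
    y = blocks %/% ceiling(d[1] / k)
  )
  out <- grid_recording(sig, coords, rec$sampling_rate,
                        rec$spatial_scale * k, rec$t_start,
                        rec$units, rec$annotations)
  attr(out, "history") <- recording_history(rec)
  append_history(out, "spatial_downsample", list(k = k))
}

#' Welch power spectral density of one segment-windowed signal
#'
#' Hann window, per-segment linear detrending, 50% overlap, one-sided
#' density. Used by the logMUA block; exposed for testing.
#'
#' @param x numeric signal.
#' @param fs sampling rate, Hz.
#' @param nperseg samples per segment.
#' @param overlap fractional segment overlap.
#' @return list with `freq` (Hz) and `psd`.
#' @export
welch_psd <- function(x, fs, nperseg, overlap = 0.5) {
  n <- length(x)
  if (n < nperseg) stop("signal shorter than nperseg")
  noverlap <- floor(overlap * nperseg)
  step <- nperseg - noverlap
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- hann_window(nperseg)
  R <- detrend_projector(nperseg)
  seg <- vapply(starts, function(s) x[s:(s + nperseg - 1L)], numeric(nperseg))
  seg <- (R %*% seg) * w
  p <- periodogram_cols(seg, fs, w)
  list(freq = (0:(nrow(p) - 1L)) * fs / nperseg, psd = rowMeans(p))
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))

# residual-maker matrix of the regression on [1, t]: per-segment linear detrend
detrend_projector <- function(n) {
  X <- cbind(1, seq_len(n))
  diag(n) - X %*% solve(crossprod(X), t(X))
}

# one-sided periodograms of windowed segments (columns), Welch scaling
periodogram_cols <- function(seg, fs, w) {
  n <- nrow(seg)
  sp <- Mod(stats::mvfft(seg))^2 / (fs * sum(w^2))
  half <- floor(n / 2) + 1L
  sp <- sp[seq_len(half), , drop = FALSE]
  dbl <- 2:(if (n %% 2 == 0) half - 1L else half)
  sp[dbl, ] <- 2 * sp[dbl, ]
  sp
}

#' Logarithmic multi-unit activity estimate
#'
#' Converts a broadband recording into a logMUA signal at a reduced rate:
#' a moving window samples the recording at `mua_rate`; in each window the
#' power spectral density is estimated with Welch's method
#' (`nperseg = round(sampling_rate / band[1])` samples per segment,
#' `noverlap = floor(0.5 * nperseg)`, Hann window, linear detrending); the
#' MUA is the mean in-band power divided by the mean full-spectrum power,
#' and the output is its natural logarithm. Slow up/down alternation makes
#' the logMUA amplitude distribution bimodal, which the threshold trigger
#' detector exploits.
#'
#' Windows are centered on the output sample times; windows overhanging the
#' recording edges are truncated (noted in the history), not zero-padded.
#'
#' @param rec a broadband [grid_recording()] with
#'   `sampling_rate > 2 * band[2]`.
#' @param band high-frequency band `(f_low, f_high)` in Hz.
#' @param window_size moving-window length, s; must be `>= 1 / band[1]`.
#' @param mua_rate output sampling rate, Hz; must be `>= 1 / window_size`.
#' @return a [grid_recording()] of logMUA signals at `mua_rate`.
#' @export
logmua_estimate <- function(rec, band = c(200, 1500), window_size = 0.3,
                            mua_rate = 100) {
  fs <- rec$sampling_rate
  if (window_size < 1 / band[1]) stop("window_size must be >= 1/band[1]")
  if (mua_rate < 1 / window_size) stop("mua_rate must be >= 1/window_size")
  if (fs <= 2 * band[2]) stop("sampling_rate must exceed 2 * band[2]")
  nperseg <- round(fs / band[1])
  wlen <- round(window_size * fs)
  if (wlen < nperseg) stop("window shorter than nperseg")
  noverlap <- floor(0.5 * nperseg)
  step_seg <- nperseg - noverlap
  n <- n_samples(rec)
  n_out <- floor(n / fs * mua_rate)
  centers <- round((seq_len(n_out) - 1) / mua_rate * fs) + 1L
  starts <- centers - wlen %/% 2L
  full <- starts >= 1L & (starts + wlen - 1L) <= n

  freq <- (0:(floor(nperseg / 2))) * fs / nperseg
  in_band <- freq >= band[1] & freq <= band[2]
  w <- hann_window(nperseg)
  R <- detrend_projector(nperseg)
  rel <- seq(0L, wlen - nperseg, by = step_seg)          # segment offsets in window
  m <- length(rel)

  ratio_from_psd <- function(psd_cols) {
    mean(psd_cols[in_band]) / mean(psd_cols)
  }

  out <- matrix(NA_real_, n_channels(rec), n_out)
  seg_idx <- outer(0:(nperseg - 1L), as.vector(outer(rel, starts[full], "+")), "+")
  for (ch in seq_len(n_channels(rec))) {
    s <- rec$signals[ch, ]
    if (any(full)) {
      seg <- matrix(s[seg_idx], nrow = nperseg)
      seg <- (R %*% seg) * w
      p <- periodogram_cols(seg, fs, w)
      parr <- array(p, c(length(freq), m, sum(full)))
      psd_win <- apply(parr, c(1L, 3L), mean)
      out[ch, full] <- log(colMeans(psd_win[in_band, , drop = FALSE]) /
                             colMeans(psd_win))
    }
    for (k in which(!full)) {
      a <- max(1L, starts[k]); b <- min(n, starts[k] + wlen - 1L)
      ps <- welch_psd(s[a:b], fs, nperseg)$psd
      out[ch, k] <- log(ratio_from_psd(ps))
    }
  }
  res <- grid_recording(out, rec$coords, mua_rate, rec$spatial_scale,
                        rec$t_start, "logMUA", rec$annotations,
                        rec$channel_mask)
  attr(res, "history") <- recording_history(rec)
  append_history(res, "logmua_estimate",
                 list(band = band, window_size = window_size,
                      mua_rate = mua_rate, nperseg = nperseg,
                      edge_windows_truncated = sum(!full)))
}
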