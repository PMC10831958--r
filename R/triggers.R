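#' Trigger tables
#'
#' All trigger detectors return a tidy tibble with one row per detected
#' state transition: columns `channel`, `x`, `y`, `time` (s) and `state`
#' (`"up"` or `"down"`). Per channel the times are strictly increasing and,
#' when both states are present, up and down alternate. The detector name
#' and parameters travel in attributes `"detector"` and `"params"`.
#'
#' @name trigger_set
NULL

new_trigger_set <- function(df, rec, detector, params) {
  out <- tibble::as_tibble(df)
  out <- dplyr::arrange(out, .data$channel, .data$time)
  attr(out, "detector") <- detector
  attr(out, "params") <- params
  attr(out, "sampling_rate") <- rec$sampling_rate
  attr(out, "spatial_scale") <- rec$spatial_scale
  class(out) <- c("trigger_set", class(out))
  out
}

#' Analytic signal via the Hilbert transform
#'
#' FFT construction of the analytic signal `x + i H(x)`; its argument is the
#' instantaneous phase, with phase 0 at the signal peak and -pi/2 on the
#' rising flank (the upstroke) — the convention the Hilbert-phase trigger
#' detector relies on.
#'
#' @param x real numeric vector.
#' @return complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# upward level crossings with linear sub-sample interpolation
up_crossings <- function(s, tt, level) {
  i <- which(s[-length(s)] < level & s[-1] >= level)
  if (!length(i)) return(numeric(0))
  tt[i] + (level - s[i]) / (s[i + 1] - s[i]) * (tt[i + 1] - tt[i])
}

down_crossings <- function(s, tt, level) {
  i <- which(s[-length(s)] >= level & s[-1] < level)
  if (!length(i)) return(numeric(0))
  tt[i] + (s[i] - level) / (s[i] - s[i + 1]) * (tt[i + 1] - tt[i])
}

#' Fit a two-Gaussian mixture and return the inter-mode threshold
#'
#' Fits the sum of two Gaussians to the amplitude sample (EM, k-means
#' initialization of the means) and returns the location of the minimum of
#' the fitted mixture density between the two component means — the
#' separating threshold between down- and up-state amplitudes.
#'
#' @param samples numeric amplitude sample, `length >= 100`.
#' @param max_iter,tol EM iteration controls.
#' @return threshold (scalar) with attribute `"fit"` (means, sds, weights).
#' @export
fit_bimodal_threshold <- function(samples, max_iter = 300, tol = 1e-8) {
  samples <- samples[is.finite(samples)]
  if (length(samples) < 100) stop("need at least 100 samples")
  km <- stats::kmeans(samples, centers = 2, nstart = 5)
  mu <- sort(km$centers[, 1])
  sdv <- rep(stats::sd(samples) / 2, 2)
  w <- c(0.5, 0.5)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * stats::dnorm(samples, mu[1], sdv[1])
    d2 <- w[2] * stats::dnorm(samples, mu[2], sdv[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    r <- d1 / tot
    w <- c(mean(r), 1 - mean(r))
    mu <- c(sum(r * samples) / sum(r), sum((1 - r) * samples) / sum(1 - r))
    sdv <- sqrt(c(sum(r * (samples - mu[1])^2) / sum(r),
                  sum((1 - r) * (samples - mu[2])^2) / sum(1 - r)))
    sdv <- pmax(sdv, 1e-12)
    ll <- sum(log(tot))
    if (is.finite(ll) && abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  ord <- order(mu)
  mu <- mu[ord]; sdv <- sdv[ord]; w <- w[ord]
  if (diff(mu) < sum(sdv)) stop("no bimodal structure")
  mix <- function(x) w[1] * stats::dnorm(x, mu[1], sdv[1]) +
    w[2] * stats::dnorm(x, mu[2], sdv[2])
  thr <- stats::optimize(mix, interval = mu)$minimum
  attr(thr, "fit") <- list(means = mu, sds = sdv, weights = w)
  thr
}

#' Threshold from a Gaussian fit of the left (down-state) histogram peak
#'
#' Locates the first dominant peak of the amplitude distribution, fits a
#' Gaussian to the samples left of it (half-sample folding: the peak is the
#' mean, the spread is estimated from the left tail), and returns
#' `mean + sd * sigma_factor`. Robust when the up-state mode is weak or
#' absent.
#'
#' @param samples numeric amplitude sample.
#' @param sigma_factor user-set multiple of the fitted standard deviation.
#' @param min_height local maxima of the smoothed amplitude density below
#'   this fraction of the global maximum are not counted as peaks.
#' @return threshold (scalar).
#' @export
fit_left_peak_threshold <- function(samples, sigma_factor = 3, min_height = 0.2) {
  samples <- samples[is.finite(samples)]
  den <- stats::density(samples)
  y <- den$y
  locmax <- which(diff(sign(diff(y))) == -2) + 1L
  locmax <- locmax[y[locmax] >= min_height * max(y)]
  if (!length(locmax)) stop("peak at histogram edge")
  peak <- den$x[locmax[1]]
  left <- samples[samples <= peak]
  if (length(left) < 2) stop("peak at histogram edge")
  sdv <- sqrt(mean((left - peak)^2))
  peak + sdv * sigma_factor
}

#' Detect state transitions by amplitude thresholding
#'
#' Finds, per channel, the upward and downward crossings of a channel-wise
#' threshold. The threshold is either fixed, the central minimum of a
#' two-Gaussian fit of the amplitude distribution ([fit_bimodal_threshold()];
#' the standard choice for logMUA signals), or the left-peak variant
#' ([fit_left_peak_threshold()]). With `method = "bimodal_fit"`, channels
#' whose fit finds no bimodal structure fall back to the left-peak fit.
#' Crossing times are linearly interpolated between samples; up and down
#' alternate per channel by construction.
#'
#' @param rec a [grid_recording()] (typically logMUA).
#' @param method threshold rule.
#' @param fixed_value threshold for `method = "fixed"`.
#' @param sigma_factor for the left-peak rule / fallback.
#' @return a trigger tibble (see [trigger_set]) with `"up"` and `"down"` rows.
#' @export
detect_threshold_triggers <- function(rec,
                                      method = c("bimodal_fit", "left_peak", "fixed"),
                                      fixed_value = NULL, sigma_factor = 3) {
  method <- match.arg(method)
  tt <- sample_times(rec)
  n_fallback <- 0L
  rows <- purrr::map_dfr(which(rec$channel_mask), function(ch) {
    s <- rec$signals[ch, ]
    thr <- switch(method,
      fixed = fixed_value,
      left_peak = fit_left_peak_threshold(s, sigma_factor),
      bimodal_fit = tryCatch(as.numeric(fit_bimodal_threshold(s)),
        error = function(e) {
          n_fallback <<- n_fallback + 1L
          fit_left_peak_threshold(s, sigma_factor)
        })
    )
    ups <- up_crossings(s, tt, thr)
    downs <- down_crossings(s, tt, thr)
    ev <- rbind(
      data.frame(time = ups, state = rep("up", length(ups))),
      data.frame(time = downs, state = rep("down", length(downs)))
    )
    ev <- ev[order(ev$time), , drop = FALSE]
    while (nrow(ev) && ev$state[1] == "down") ev <- ev[-1, , drop = FALSE]
    if (!nrow(ev)) return(NULL)
    tibble::tibble(channel = ch, x = rec$coords$x[ch], y = rec$coords$y[ch],
                   time = ev$time, state = ev$state)
  })
  if (!nrow(rows)) {
    rows <- tibble::tibble(channel = integer(), x = integer(), y = integer(),
                           time = numeric(), state = character())
  }
  new_trigger_set(rows, rec, "threshold",
                  list(method = method, sigma_factor = sigma_factor,
                       fixed_value = fixed_value, n_fallback = n_fallback))
}

#' Remove up/down states shorter than a minimum duration
#'
#' Drops up states (`up -> down` interval) shorter than `min_up` and down
#' states (`down -> up` interval) shorter than `min_down`; in each case both
#' bounding events are removed, which merges the neighboring states, so
#' alternation is preserved.
#'
#' @param ts a trigger tibble with both up and down states.
#' @param min_up,min_down minimal state durations, s.
#' @return the filtered trigger tibble.
#' @export
filter_min_state_durations <- function(ts, min_up = 0, min_down = 0) {
  filt <- function(ev) {
    # drop short up states
    repeat {
      i <- which(ev$state == "up")
      short <- i[i < nrow(ev) & ev$state[pmin(i + 1L, nrow(ev))] == "down" &
                   ev$time[pmin(i + 1L, nrow(ev))] - ev$time[i] < min_up]
      if (!length(short)) break
      ev <- ev[-c(short[1], short[1] + 1L), , drop = FALSE]
    }
    # drop short down states
    repeat {
      i <- which(ev$state == "down")
      short <- i[i < nrow(ev) & ev$state[pmin(i + 1L, nrow(ev))] == "up" &
                   ev$time[pmin(i + 1L, nrow(ev))] - ev$time[i] < min_down]
      if (!length(short)) break
      ev <- ev[-c(short[1], short[1] + 1L), , drop = FALSE]
    }
    ev
  }
  out <- ts |>
    dplyr::group_by(.data$channel) |>
    dplyr::group_modify(~ filt(.x)) |>
    dplyr::ungroup()
  out <- out[, names(ts)]
  for (a in c("detector", "params", "sampling_rate", "spatial_scale")) {
    attr(out, a) <- attr(ts, a)
  }
  attr(out, "params") <- c(attr(ts, "params"),
                           list(min_up = min_up, min_down = min_down))
  class(out) <- class(ts)
  out
}

#' Detect upstrokes from the Hilbert phase
#'
#' Computes the instantaneous phase of each channel's analytic signal and
#' marks an upward trigger at each upward crossing of `phase_threshold`
#' (default -pi/2, the beginning of the upstroke), retained only if the
#' phase reaches its peak (an upward crossing of 0) before the next
#' threshold crossing. Signals must be detrended and z-scored beforehand —
#' offsets or drift corrupt the phase.
#'
#' @param rec a processed [grid_recording()].
#' @param phase_threshold phase level in radians.
#' @return a trigger tibble of `"up"` rows.
#' @export
detect_hilbert_triggers <- function(rec, phase_threshold = -pi / 2) {
  tt <- sample_times(rec)
  rows <- purrr::map_dfr(which(rec$channel_mask), function(ch) {
    s <- rec$signals[ch, ]
    if (all(!is.finite(s)) || stats::sd(s) == 0) return(NULL)
    phi <- Arg(analytic_signal(s))
    # crossings computed on the continuous (non-wrapping) part only
    i <- which(phi[-length(phi)] < phase_threshold &
                 phi[-1] >= phase_threshold &
                 (phi[-1] - phi[-length(phi)]) < pi)
    if (!length(i)) return(NULL)
    t_cross <- tt[i] + (phase_threshold - phi[i]) / (phi[i + 1] - phi[i]) *
      (tt[i + 1] - tt[i])
    zero_up <- which(phi[-length(phi)] < 0 & phi[-1] >= 0 &
                       (phi[-1] - phi[-length(phi)]) < pi)
    bounds <- c(i, length(phi) + 1L)
    keep <- vapply(seq_along(i), function(k) {
      any(zero_up > i[k] & zero_up < bounds[k + 1L])
    }, logical(1))
    if (!any(keep)) return(NULL)
    tibble::tibble(channel = ch, x = rec$coords$x[ch], y = rec$coords$y[ch],
                   time = t_cross[keep], state = "up")
  })
  if (!nrow(rows)) {
    rows <- tibble::tibble(channel = integer(), x = integer(), y = integer(),
                           time = numeric(), state = character())
  }
  new_trigger_set(rows, rec, "hilbert",
                  list(phase_threshold = phase_threshold))
}

#' Detect transition onsets as refined local minima
#'
#' A local minimum followed by a sufficiently high peak marks the start of
#' an upward transition. Candidates are refined by three rules: (1) peak
#' candidates must exceed a relative amplitude threshold computed in a
#' moving window; (2) accepted peaks must be separated by a minimum
#' distance; (3) a minimum must be followed by a monotonically rising signal
#' for a set interval. When several minima fall between two accepted peaks,
#' the last one before the following peak is used. Minima are reported at
#' sample resolution.
#'
#' @param rec a processed [grid_recording()].
#' @param window moving-window length for the relative peak threshold, s.
#' @param rel_threshold fraction of the window's amplitude range a peak must
#'   exceed (above the window minimum).
#' @param min_peak_distance minimal separation of accepted peaks, s.
#' @param rise_interval required monotonic-rise duration after a minimum, s.
#' @return a trigger tibble of `"up"` rows.
#' @export
detect_minima_triggers <- function(rec, window = 2, rel_threshold = 0.5,
                                   min_peak_distance = 1, rise_interval = 0.1) {
  stopifnot(window > 0, min_peak_distance > 0, rise_interval > 0)
  fs <- rec$sampling_rate
  tt <- sample_times(rec)
  halfw <- max(1L, round(window * fs / 2))
  rise_n <- max(1L, round(rise_interval * fs))
  min_dist_n <- round(min_peak_distance * fs)
  rows <- purrr::map_dfr(which(rec$channel_mask), function(ch) {
    s <- rec$signals[ch, ]
    n <- length(s)
    ds <- diff(s)
    pk <- which(ds[-length(ds)] > 0 & ds[-1] <= 0) + 1L
    if (!length(pk)) return(NULL)
    # rule 1: relative amplitude threshold within the moving window
    ok1 <- vapply(pk, function(i) {
      win <- s[max(1L, i - halfw):min(n, i + halfw)]
      s[i] >= min(win) + rel_threshold * (max(win) - min(win))
    }, logical(1))
    pk <- pk[ok1]
    if (!length(pk)) return(NULL)
    # rule 2: minimum peak separation, higher peaks take precedence
    acc <- integer(0)
    for (i in pk[order(s[pk], decreasing = TRUE)]) {
      if (!length(acc) || all(abs(acc - i) >= min_dist_n)) acc <- c(acc, i)
    }
    acc <- sort(acc)
    # minima between consecutive accepted peaks (and before the first peak);
    # non-strict on the left so a flat baseline before a rise still counts
    mins <- which(ds[-length(ds)] <= 0 & ds[-1] > 0) + 1L
    bounds <- c(0L, acc)
    trig <- purrr::map_int(seq_along(acc), function(k) {
      cand <- mins[mins > bounds[k] & mins < acc[k]]
      # rule 3: strictly monotonic rise for rise_interval after the minimum
      cand <- cand[vapply(cand, function(i) {
        j <- min(n, i + rise_n)
        all(diff(s[i:j]) > 0)
      }, logical(1))]
      if (!length(cand)) NA_integer_ else max(cand)   # last before the peak
    })
    trig <- trig[!is.na(trig)]
    if (!length(trig)) return(NULL)
    tibble::tibble(channel = ch, x = rec$coords$x[ch], y = rec$coords$y[ch],
                   time = tt[trig], state = "up")
  })
  if (!nrow(rows)) {
    rows <- tibble::tibble(channel = integer(), x = integer(), y = integer(),
                           time = numeric(), state = character())
  }
  new_trigger_set(rows, rec, "minima",
                  list(window = window, rel_threshold = rel_threshold,
                       min_peak_distance = min_peak_distance,
                       rise_interval = rise_interval))
}
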