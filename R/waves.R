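#' Time-to-space scaling for trigger clustering
#'
#' Waves are clusters of triggers in the space (x, y, scaled time). A wave
#' propagating at reference velocity `v0` is isotropic in that space when
#' one frame of time is worth `v0 / (sampling_rate * spatial_scale)` grid
#' units. For wide-field imaging at 25 Hz and 0.05 mm pitch the expected
#' 10-20 mm/s propagation maps to ratios of 8-16 grid units per frame.
#'
#' @param v0 expected propagation velocity, mm/s.
#' @param sampling_rate Hz.
#' @param spatial_scale inter-site spacing, mm.
#' @return the scaling ratio, grid units per frame.
#' @examples
#' compute_time_space_ratio(10, 25, 0.05)  # 8
#' compute_time_space_ratio(20, 25, 0.05)  # 16
#' @export
compute_time_space_ratio <- function(v0, sampling_rate, spatial_scale) {
  if (any(c(v0, sampling_rate, spatial_scale) <= 0)) {
    stop("all inputs must be > 0")
  }
  v0 / (sampling_rate * spatial_scale)
}

#' Noise label used for unclustered triggers
#' @export
NOISE_LABEL <- -1L

# exact DBSCAN (brute-force region queries); labels: -1 noise, 1..K clusters
dbscan_points <- function(pts, eps, min_pts) {
  n <- nrow(pts)
  eps2 <- eps^2
  labels <- rep(NA_integer_, n)
  visited <- rep(FALSE, n)
  query <- function(i) {
    d2 <- (pts[, 1] - pts[i, 1])^2 + (pts[, 2] - pts[i, 2])^2 +
      (pts[, 3] - pts[i, 3])^2
    which(d2 <= eps2)
  }
  k <- 0L
  for (i in seq_len(n)) {
    if (visited[i]) next
    visited[i] <- TRUE
    nb <- query(i)
    if (length(nb) < min_pts) {
      labels[i] <- NOISE_LABEL
      next
    }
    k <- k + 1L
    labels[i] <- k
    seeds <- setdiff(nb, i)
    while (length(seeds)) {
      q <- seeds[1]
      seeds <- seeds[-1]
      if (is.na(labels[q]) || labels[q] == NOISE_LABEL) labels[q] <- k
      if (!visited[q]) {
        visited[q] <- TRUE
        nbq <- query(q)
        if (length(nbq) >= min_pts) {
          seeds <- c(seeds, nbq[is.na(labels[nbq]) |
                                  (labels[nbq] == NOISE_LABEL & !visited[nbq])])
          seeds <- unique(seeds)
        }
      }
    }
  }
  labels
}

#' Group triggers into propagating waves
#'
#' Embeds each upward trigger at `(x, y, t_frames * time_space_ratio)` and
#' runs density-based clustering (DBSCAN semantics: `eps =
#' neighbour_distance` grid units, `min_pts = min_samples_per_wave`).
#' Triggers in no dense region get the noise label `-1`; wave ids are
#' renumbered in order of each wave's first trigger time.
#'
#' @param ts a trigger tibble (only `"up"` rows are clustered).
#' @param time_space_ratio grid units per frame; see
#'   [compute_time_space_ratio()].
#' @param neighbour_distance DBSCAN epsilon, grid units.
#' @param min_samples_per_wave minimum triggers per wave.
#' @param sampling_rate frames per second used to convert trigger times to
#'   frames; defaults to the rate recorded on `ts`.
#' @return a wave tibble: `ts` with a `wave` column (class `wave_set`).
#' @export
cluster_triggers_to_waves <- function(ts, time_space_ratio,
                                      neighbour_distance = 4,
                                      min_samples_per_wave = 10,
                                      sampling_rate = attr(ts, "sampling_rate")) {
  stopifnot(time_space_ratio > 0, neighbour_distance > 0,
            min_samples_per_wave > 0)
  up <- dplyr::filter(ts, .data$state == "up")
  if (!nrow(up)) stop("no upward triggers to cluster")
  pts <- cbind(up$x, up$y, up$time * sampling_rate * time_space_ratio)
  labels <- dbscan_points(pts, neighbour_distance, min_samples_per_wave)
  # renumber wave ids by first trigger time
  first_t <- tapply(up$time[labels > 0], labels[labels > 0], min)
  remap <- integer(max(0L, max(labels)))
  remap[as.integer(names(sort(first_t)))] <- seq_along(first_t)
  wave_lab <- rep(NOISE_LABEL, length(labels))
  wave_lab[labels > 0] <- remap[labels[labels > 0]]
  up$wave <- wave_lab
  out <- tibble::as_tibble(up)
  attr(out, "params") <- list(time_space_ratio = time_space_ratio,
                              neighbour_distance = neighbour_distance,
                              min_samples_per_wave = min_samples_per_wave)
  attr(out, "sampling_rate") <- sampling_rate
  attr(out, "spatial_scale") <- attr(ts, "spatial_scale")
  class(out) <- c("wave_set", setdiff(class(out), "wave_set"))
  out
}

#' Keep one trigger per channel within each wave
#'
#' The delay map T(x, y) must be single-valued, so by default each channel
#' contributes only its earliest trigger to a wave. `keep_all` leaves the
#' labeling untouched (delay-map construction will then refuse duplicated
#' channels).
#'
#' @param ws a wave tibble.
#' @param policy `"keep_earliest"` or `"keep_all"`.
#' @return the deduplicated wave tibble.
#' @export
dedupe_channel_triggers <- function(ws, policy = c("keep_earliest", "keep_all")) {
  policy <- match.arg(policy)
  if (policy == "keep_all") return(ws)
  out <- ws |>
    dplyr::group_by(.data$wave, .data$channel) |>
    dplyr::slice_min(.data$time, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$channel, .data$time)
  for (a in c("params", "sampling_rate", "spatial_scale")) {
    attr(out, a) <- attr(ws, a)
  }
  class(out) <- class(ws)
  out
}

#' Arrange per-channel phase signals on the grid
#'
#' Returns the instantaneous (analytic-signal) phase of every channel as a
#' `[n_frames, n_y, n_x]` array; empty sites are NaN. Input signals should
#' be detrended and z-scored.
#'
#' @param rec a processed [grid_recording()].
#' @return numeric array with attributes `sampling_rate`, `t_start`,
#'   `spatial_scale`.
#' @export
phase_field <- function(rec) {
  d <- grid_dims(rec)
  n_t <- n_samples(rec)
  arr <- array(NaN, c(n_t, d[2], d[1]))
  for (ch in which(rec$channel_mask)) {
    arr[, rec$coords$y[ch] + 1L, rec$coords$x[ch] + 1L] <-
      Arg(analytic_signal(rec$signals[ch, ]))
  }
  attr(arr, "sampling_rate") <- rec$sampling_rate
  attr(arr, "t_start") <- rec$t_start
  attr(arr, "spatial_scale") <- rec$spatial_scale
  arr
}

# 3x3 convolution of a [T, ny, nx] array, edge-replicated, frame-vectorized.
# NaNs propagate to every site whose stencil touches them.
conv3x3 <- function(a, k) {
  ny <- dim(a)[2]; nx <- dim(a)[3]
  out <- array(0, dim(a))
  for (di in -1:1) for (dj in -1:1) {
    w <- k[di + 2, dj + 2]
    if (w == 0) next
    iy <- pmin(pmax(seq_len(ny) + di, 1L), ny)
    ix <- pmin(pmax(seq_len(nx) + dj, 1L), nx)
    out <- out + w * a[, iy, ix, drop = FALSE]
  }
  out
}

scharr_x <- matrix(c(-3, 0, 3, -10, 0, 10, -3, 0, 3), 3, byrow = TRUE) / 32
scharr_y <- matrix(c(-3, -10, -3, 0, 0, 0, 3, 10, 3), 3, byrow = TRUE) / 32
hs_avg <- matrix(c(1, 2, 1, 2, 0, 2, 1, 2, 1), 3, byrow = TRUE) / 12

# 1D Gaussian smoothing along one margin of a 3D array (NaN-aware)
gauss_smooth_dim <- function(a, sigma, dim_i) {
  if (sigma <= 0) return(a)
  r <- max(1L, ceiling(3 * sigma))
  w <- stats::dnorm(-r:r, sd = sigma)
  n <- dim(a)[dim_i]
  num <- array(0, dim(a)); den <- array(0, dim(a))
  val <- a; val[is.na(val)] <- 0
  ok <- !is.na(a)
  for (s in -r:r) {
    idx <- pmin(pmax(seq_len(n) + s, 1L), n)
    sl <- switch(dim_i,
                 list(idx, TRUE, TRUE), list(TRUE, idx, TRUE), list(TRUE, TRUE, idx))
    num <- num + w[s + r + 1] * do.call(`[`, c(list(val), sl, drop = FALSE))
    den <- den + w[s + r + 1] * do.call(`[`, c(list(ok * 1), sl, drop = FALSE))
  }
  out <- num / den
  out[!ok] <- NaN
  out
}

#' Horn-Schunck optical flow of a phase (or amplitude) field
#'
#' Estimates the apparent motion of the activity pattern by iteratively
#' minimizing the Horn-Schunck functional (brightness constancy plus
#' `alpha^2`-weighted smoothness, both with quadratic penalty). Spatial
#' derivatives use a 3x3 Scharr filter; for phase input all derivatives are
#' taken as wrapped angular differences (computed through the unit phasor
#' `exp(i * phase)`), so the flow is exact across the +/-pi seam and
#' invariant to adding 2 pi to the field. The converged field is smoothed
#' with a Gaussian kernel in space and time.
#'
#' @param field `[n_frames, n_y, n_x]` array from [phase_field()] (or an
#'   amplitude field with `source = "amplitude"`).
#' @param alpha smoothness weight (default 1.5).
#' @param source `"phase"` or `"amplitude"`.
#' @param max_iter,tol iteration cap and mean-square update tolerance.
#' @param smooth_sigma Gaussian post-smoothing widths
#'   `c(space = sites, time = frames)`.
#' @return a `flow_field` list: `u`, `v` (`[n_frames, n_y, n_x]`, grid units
#'   per frame; the last frame repeats the final pair estimate) and `params`
#'   (including `converged`).
#' @export
compute_optical_flow <- function(field, alpha = 1.5,
                                 source = c("phase", "amplitude"),
                                 max_iter = 500, tol = 1e-6,
                                 smooth_sigma = c(space = 1, time = 1)) {
  source <- match.arg(source)
  stopifnot(alpha > 0, tol > 0, dim(field)[1] >= 2)
  nt <- dim(field)[1]
  pair <- function(a) a[-nt, , , drop = FALSE]   # frames 1..nt-1
  nxt <- function(a) a[-1, , , drop = FALSE]     # frames 2..nt
  if (source == "phase") {
    zr <- cos(field); zi <- sin(field)
    # d(phase)/dx = Im(conj(z) dz/dx), z on the unit circle
    gx <- zr * conv3x3(zi, scharr_x) - zi * conv3x3(zr, scharr_x)
    gy <- zr * conv3x3(zi, scharr_y) - zi * conv3x3(zr, scharr_y)
    Ex <- (pair(gx) + nxt(gx)) / 2
    Ey <- (pair(gy) + nxt(gy)) / 2
    Et <- atan2(nxt(zi) * pair(zr) - nxt(zr) * pair(zi),
                nxt(zr) * pair(zr) + nxt(zi) * pair(zi))
  } else {
    gx <- conv3x3(field, scharr_x)
    gy <- conv3x3(field, scharr_y)
    Ex <- (pair(gx) + nxt(gx)) / 2
    Ey <- (pair(gy) + nxt(gy)) / 2
    Et <- nxt(field) - pair(field)
  }
  valid <- is.finite(Ex) & is.finite(Ey) & is.finite(Et)
  Ex[!valid] <- 0; Ey[!valid] <- 0; Et[!valid] <- 0
  denom <- alpha^2 + Ex^2 + Ey^2
  u <- array(0, dim(Ex)); v <- array(0, dim(Ex))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    ub <- conv3x3(u, hs_avg)
    vb <- conv3x3(v, hs_avg)
    common <- (Ex * ub + Ey * vb + Et) / denom
    u_new <- ub - Ex * common
    v_new <- vb - Ey * common
    delta <- mean((u_new - u)^2 + (v_new - v)^2)
    u <- u_new; v <- v_new
    if (delta < tol) { converged <- TRUE; break }
  }
  u[!valid] <- NaN; v[!valid] <- NaN
  u <- gauss_smooth_dim(gauss_smooth_dim(gauss_smooth_dim(
    u, smooth_sigma[["time"]], 1L), smooth_sigma[["space"]], 2L),
    smooth_sigma[["space"]], 3L)
  v <- gauss_smooth_dim(gauss_smooth_dim(gauss_smooth_dim(
    v, smooth_sigma[["time"]], 1L), smooth_sigma[["space"]], 2L),
    smooth_sigma[["space"]], 3L)
  # extend pairwise estimates to one field per frame
  u <- u[c(seq_len(nt - 1), nt - 1), , , drop = FALSE]
  v <- v[c(seq_len(nt - 1), nt - 1), , , drop = FALSE]
  if (!converged) warning("optical flow did not converge in ", max_iter,
                          " iterations")
  structure(
    list(u = u, v = v,
         params = list(alpha = alpha, source = source, max_iter = max_iter,
                       tol = tol, smooth_sigma = smooth_sigma,
                       converged = converged, iterations = it,
                       sampling_rate = attr(field, "sampling_rate"),
                       t_start = attr(field, "t_start") %||% 0)),
    class = "flow_field"
  )
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf("<flow_field> %d frames, %dx%d grid, alpha = %g, %s\n",
              dim(x$u)[1], dim(x$u)[3], dim(x$u)[2], x$params$alpha,
              if (x$params$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Channel-wise wave directions from the optical flow
#'
#' Attaches to every clustered trigger the optical-flow vector at its grid
#' site in the frame nearest its trigger time: columns `flow_u`, `flow_v`,
#' `flow_mag` and `direction` (radians, `atan2(v, u)`). Triggers at sites
#' with undefined (NaN or zero) flow are dropped; their count is reported
#' in `attr(, "n_skipped")`.
#'
#' @param ws a wave tibble.
#' @param flow a `flow_field` from [compute_optical_flow()].
#' @return the wave tibble with direction columns.
#' @export
wave_directions_from_flow <- function(ws, flow) {
  fs <- flow$params$sampling_rate
  t0 <- flow$params$t_start
  nt <- dim(flow$u)[1]
  frame <- pmin(pmax(round((ws$time - t0) * fs) + 1L, 1L), nt)
  idx <- cbind(frame, ws$y + 1L, ws$x + 1L)
  u <- flow$u[idx]; v <- flow$v[idx]
  mag <- sqrt(u^2 + v^2)
  ok <- is.finite(mag) & mag > 0
  out <- ws
  out$flow_u <- u; out$flow_v <- v; out$flow_mag <- mag
  out$direction <- atan2(v, u)
  out <- out[ok, , drop = FALSE]
  for (a in c("params", "sampling_rate", "spatial_scale")) {
    attr(out, a) <- attr(ws, a)
  }
  class(out) <- class(ws)
  attr(out, "n_skipped") <- sum(!ok)
  out
}

#' Cluster waves into recurring propagation modes
#'
#' Builds the trigger-delay matrix (one row per wave, one column per
#' channel, entries = trigger time minus the wave's earliest trigger;
#' channels a wave never reaches are imputed with that wave's maximum delay
#' — "late" — or with the mean) and k-means-clusters its rows. The number
#' of modes is chosen by the user. Mode ids are ordered by cluster size,
#' largest first.
#'
#' @param ws a wave tibble (deduplicated per channel).
#' @param k number of modes, `1 <= k <=` number of waves.
#' @param impute `"max"` or `"mean"` for channels missing from a wave.
#' @param seed RNG seed for k-means restarts.
#' @param nstart k-means restarts.
#' @return the wave tibble with a `mode` column; attributes
#'   `"mode_centers"` (delay-matrix centroids) and `"mode_separation"`
#'   (between-cluster sum of squares fraction).
#' @export
cluster_wave_modes <- function(ws, k, impute = c("max", "mean"),
                               seed = 0, nstart = 10) {
  impute <- match.arg(impute)
  real <- dplyr::filter(ws, .data$wave != NOISE_LABEL)
  wave_ids <- sort(unique(real$wave))
  if (k > length(wave_ids)) stop("k exceeds the number of waves")
  channels <- sort(unique(real$channel))
  delays <- real |>
    dplyr::group_by(.data$wave) |>
    dplyr::mutate(delay = .data$time - min(.data$time)) |>
    dplyr::ungroup()
  M <- matrix(NA_real_, length(wave_ids), length(channels),
              dimnames = list(wave_ids, channels))
  M[cbind(match(delays$wave, wave_ids), match(delays$channel, channels))] <-
    delays$delay
  for (i in seq_len(nrow(M))) {
    fill <- if (impute == "max") max(M[i, ], na.rm = TRUE) else mean(M[i, ], na.rm = TRUE)
    M[i, is.na(M[i, ])] <- fill
  }
  set.seed(seed)
  fit <- tryCatch(
    stats::kmeans(M, centers = k, nstart = nstart),
    error = function(e) {
      # degenerate input (fewer distinct delay patterns than k): one cluster
      list(cluster = rep(1L, nrow(M)), centers = M[1, , drop = FALSE],
           betweenss = 0, totss = max(sum(scale(M, scale = FALSE)^2), 1e-300))
    }
  )
  sizes <- table(fit$cluster)
  remap <- integer(max(fit$cluster))
  remap[as.integer(names(sort(sizes, decreasing = TRUE)))] <-
    seq_along(sizes)
  modes <- tibble::tibble(wave = wave_ids, mode = remap[fit$cluster])
  out <- dplyr::left_join(ws, modes, by = "wave")
  for (a in c("params", "sampling_rate", "spatial_scale")) {
    attr(out, a) <- attr(ws, a)
  }
  class(out) <- class(ws)
  attr(out, "mode_centers") <- fit$centers
  # identical delay patterns leave only float residue in the sums of
  # squares; report zero separation instead of a 0/0 artifact
  total <- sum(scale(M, scale = FALSE)^2)
  attr(out, "mode_separation") <-
    if (total < 1e-12) 0 else fit$betweenss / fit$totss
  out
}
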