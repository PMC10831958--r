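#' Delay map of one wave
#'
#' The delay function T(x, y) gives, for each grid site the wave reached,
#' the arrival time relative to the wave's onset (its earliest trigger);
#' sites without a trigger are NaN. Its spatial gradient magnitude is the
#' inverse local speed.
#'
#' @param ws a wave tibble, deduplicated per channel
#'   ([dedupe_channel_triggers()]).
#' @param wave_id which wave.
#' @param dims grid dimensions `c(n_x, n_y)`; defaults to the bounding box
#'   of the triggers in `ws`.
#' @return a `wave_delay_map`: list with `T` (`n_y x n_x` matrix, seconds),
#'   `spatial_scale` (mm) and `wave_id`.
#' @export
build_delay_map <- function(ws, wave_id, dims = NULL) {
  w <- dplyr::filter(ws, .data$wave == wave_id)
  if (nrow(w) < 3) stop("wave has fewer than 3 sites; gradient undefined")
  if (anyDuplicated(w$channel)) {
    stop("wave has duplicated channels; run dedupe_channel_triggers() first")
  }
  if (is.null(dims)) dims <- c(max(ws$x) + 1L, max(ws$y) + 1L)
  Tm <- matrix(NaN, nrow = dims[2], ncol = dims[1])
  Tm[cbind(w$y + 1L, w$x + 1L)] <- w$time - min(w$time)
  structure(list(T = Tm, spatial_scale = attr(ws, "spatial_scale"),
                 wave_id = wave_id),
            class = "wave_delay_map")
}

# NaN-aware spatial gradient: central differences inside, one-sided at
# edges/NaN boundaries; exact for linear T.
grad_nan <- function(Tm, h) {
  ny <- nrow(Tm); nx <- ncol(Tm)
  gx <- matrix(NaN, ny, nx); gy <- matrix(NaN, ny, nx)
  for (i in seq_len(ny)) for (j in seq_len(nx)) {
    if (!is.finite(Tm[i, j])) next
    l <- if (j > 1 && is.finite(Tm[i, j - 1])) Tm[i, j - 1] else NA
    r <- if (j < nx && is.finite(Tm[i, j + 1])) Tm[i, j + 1] else NA
    gx[i, j] <- if (!is.na(l) && !is.na(r)) (r - l) / (2 * h)
    else if (!is.na(r)) (r - Tm[i, j]) / h
    else if (!is.na(l)) (Tm[i, j] - l) / h else NaN
    d <- if (i > 1 && is.finite(Tm[i - 1, j])) Tm[i - 1, j] else NA
    u <- if (i < ny && is.finite(Tm[i + 1, j])) Tm[i + 1, j] else NA
    gy[i, j] <- if (!is.na(d) && !is.na(u)) (u - d) / (2 * h)
    else if (!is.na(u)) (u - Tm[i, j]) / h
    else if (!is.na(d)) (Tm[i, j] - d) / h else NaN
  }
  list(gx = gx, gy = gy)
}

#' Channel-wise velocity from a delay map
#'
#' Local speed `v(x, y) = 1 / sqrt((dT/dx)^2 + (dT/dy)^2)`: derivatives of
#' the delay map by central finite differences (one-sided at edges and NaN
#' boundaries), in s/mm. Sites with zero gradient get NaN (undefined, not
#' infinite); so do sites with no finite neighbor along either axis.
#'
#' @param dm a `wave_delay_map` from [build_delay_map()].
#' @return tibble with `x`, `y` (grid coords), `delay` (s), `velocity`
#'   (mm/s) and the delay-gradient direction `grad_direction` (radians,
#'   direction of propagation: arrival time increases along the direction
#'   the wave travels, so this is the direction of `+grad T`).
#' @export
channel_velocity <- function(dm) {
  g <- grad_nan(dm$T, dm$spatial_scale)
  mag <- sqrt(g$gx^2 + g$gy^2)
  vel <- 1 / mag
  vel[mag == 0] <- NaN
  keep <- which(is.finite(dm$T), arr.ind = TRUE)
  tibble::tibble(
    x = keep[, 2] - 1L, y = keep[, 1] - 1L,
    delay = dm$T[keep],
    velocity = vel[keep],
    grad_direction = atan2(g$gy[keep], g$gx[keep])
  )
}

#' Cap a velocity distribution
#'
#' Near-identical delays between distant triggers can produce unreasonably
#' large speeds; reported distributions are capped (default 120 mm/s).
#' Raw values are not altered elsewhere — this filters what is presented.
#'
#' @param values numeric velocities, mm/s.
#' @param cap maximum reported value.
#' @return the values `<= cap`; attribute `"n_capped"` counts the removals.
#' @export
cap_velocities <- function(values, cap = 120) {
  out <- values[!is.na(values) & values <= cap]
  attr(out, "n_capped") <- sum(values > cap, na.rm = TRUE)
  out
}

#' Planarity of a wave
#'
#' Alignment of a wave's channel-wise direction vectors:
#' `P = ||sum(v_i)|| / sum(||v_i||)`, between 0 (incoherent or symmetric
#' propagation, e.g. radial) and 1 (perfectly planar).
#'
#' @param u,v vector components (e.g. optical-flow vectors at the wave's
#'   triggers); alternatively `u` may be a two-column matrix or a data frame
#'   with columns `flow_u`, `flow_v`.
#' @return scalar P in `[0, 1]`.
#' @examples
#' planarity(rep(1, 10), rep(0, 10))     # 1
#' planarity(c(1, -1), c(0, 0))          # 0
#' @export
planarity <- function(u, v = NULL) {
  if (is.null(v)) {
    if (is.data.frame(u)) { v <- u$flow_v; u <- u$flow_u }
    else { v <- u[, 2]; u <- u[, 1] }
  }
  ok <- is.finite(u) & is.finite(v)
  u <- u[ok]; v <- v[ok]
  denom <- sum(sqrt(u^2 + v^2))
  if (!length(u) || denom == 0) stop("no nonzero direction vectors")
  sqrt(sum(u)^2 + sum(v)^2) / denom
}

#' Interwave intervals per channel
#'
#' Time between consecutive wave passages at each recording site: per
#' channel, successive differences of that channel's wave trigger times
#' (noise triggers excluded).
#'
#' @param ws a wave tibble.
#' @return tibble with `channel`, `x`, `y`, `interval` (s).
#' @export
interwave_intervals <- function(ws) {
  ws |>
    dplyr::filter(.data$wave != NOISE_LABEL) |>
    dplyr::group_by(.data$channel, .data$x, .data$y) |>
    dplyr::arrange(.data$time, .by_group = TRUE) |>
    dplyr::reframe(interval = diff(.data$time)) |>
    dplyr::ungroup()
}

circular_mean <- function(theta) {
  s <- mean(sin(theta)); c <- mean(cos(theta))
  r <- sqrt(s^2 + c^2)
  structure(if (r < 1e-9) NaN else atan2(s, c), resultant = r)
}

#' Hedges' effect size between two samples
#'
#' `ES = |mean(A) - mean(B)| / sd_pooled`, with
#' `sd_pooled^2 = ((N_A - 1) sd_A^2 + (N_B - 1) sd_B^2) / (N_A + N_B - 2)`
#' (sample variances, N - 1 denominators).
#'
#' @param A,B numeric samples, each of length `>= 2`.
#' @return scalar effect size.
#' @examples
#' hedges_effect_size(c(1, 2, 3), c(3, 4, 5))  # 2
#' @export
hedges_effect_size <- function(A, B) {
  nA <- length(A); nB <- length(B)
  stopifnot(nA >= 2, nB >= 2)
  sp <- sqrt(((nA - 1) * stats::var(A) + (nB - 1) * stats::var(B)) /
               (nA + nB - 2))
  if (sp == 0) stop("pooled standard deviation is zero")
  abs(mean(A) - mean(B)) / sp
}

#' Kernel density summary of a measure distribution
#'
#' Gaussian KDE with Scott's-rule bandwidth (`sd * n^(-1/5)`), except for
#' interwave intervals, which use `0.2 * sd` as the kernel size.
#'
#' @param values numeric sample with at least two distinct values.
#' @param measure_kind `"generic"` or `"interwave_interval"`.
#' @param n evaluation points.
#' @return tibble with `value`, `density`; attribute `"bandwidth"`.
#' @export
kde_summary <- function(values, measure_kind = c("generic", "interwave_interval"),
                        n = 512) {
  measure_kind <- match.arg(measure_kind)
  values <- values[is.finite(values)]
  if (length(unique(values)) < 2) stop("degenerate sample for KDE")
  bw <- if (measure_kind == "interwave_interval") {
    0.2 * stats::sd(values)
  } else {
    stats::sd(values) * length(values)^(-1 / 5)
  }
  d <- stats::density(values, bw = bw, n = n)
  out <- tibble::tibble(value = d$x, density = d$y)
  attr(out, "bandwidth") <- bw
  out
}

# per-trigger (channel-wise) measures for all waves
channel_measures <- function(ws, cap = 120) {
  real <- dplyr::filter(ws, .data$wave != NOISE_LABEL)
  if (!nrow(real)) stop("empty wave set")
  dims <- c(max(ws$x) + 1L, max(ws$y) + 1L)
  vel <- purrr::map_dfr(sort(unique(real$wave)), function(w) {
    dm <- build_delay_map(real, w, dims)
    dplyr::mutate(channel_velocity(dm), wave = w)
  })
  out <- dplyr::left_join(real, vel, by = c("wave", "x", "y"))
  iwi <- real |>
    dplyr::group_by(.data$channel) |>
    dplyr::arrange(.data$time, .by_group = TRUE) |>
    dplyr::mutate(interwave_interval = .data$time - dplyr::lag(.data$time)) |>
    dplyr::ungroup() |>
    dplyr::select("wave", "channel", "interwave_interval")
  out <- dplyr::left_join(out, iwi, by = c("wave", "channel"))
  out$velocity_capped <- !is.na(out$velocity) & out$velocity > cap
  out
}

# one-row-per-wave aggregation of channel rows
wave_measures <- function(chan_rows, cap = 120) {
  chan_rows |>
    dplyr::group_by(.data$wave) |>
    dplyr::summarise(
      n_channels = dplyr::n(),
      onset = min(.data$time),
      velocity = mean(cap_velocities(.data$velocity, cap)),
      velocity_plane_fit = plane_fit_velocity(.data$x, .data$y, .data$delay,
                                              .data$spatial_scale[1]),
      direction = if ("direction" %in% names(chan_rows)) {
        as.numeric(circular_mean(.data$direction[is.finite(.data$direction)]))
      } else NA_real_,
      planarity = if ("flow_u" %in% names(chan_rows)) {
        tryCatch(planarity(.data$flow_u, .data$flow_v), error = function(e) NA_real_)
      } else NA_real_,
      mode = if ("mode" %in% names(chan_rows)) .data$mode[1] else NA_integer_,
      .groups = "drop"
    )
}

# global plane T = a + bx x + by y (least squares); v = 1 / ||(bx, by)||
plane_fit_velocity <- function(x, y, delay, spatial_scale) {
  ok <- is.finite(delay)
  if (sum(ok) < 3) return(NA_real_)
  fit <- stats::lm.fit(cbind(1, x[ok] * spatial_scale, y[ok] * spatial_scale),
                       delay[ok])
  g <- fit$coefficients[2:3]
  m <- sqrt(sum(g^2))
  if (m == 0) NaN else 1 / m
}

#' Characterization table (stage 5)
#'
#' Emits the final tabular output: one row per wave (`"wave_wise"`) or one
#' row per wave-and-channel trigger (`"channel_wise"`), columns = measures
#' (velocity mm/s, direction rad, planarity, interwave interval s, mode)
#' plus any requested recording annotations replicated into every row.
#' Wave-wise velocity is the mean of the wave's capped channel velocities
#' (a plane-fit alternative is included as `velocity_plane_fit`); wave-wise
#' direction is the circular mean of the trigger directions.
#'
#' @param ws a wave tibble (ideally after [wave_directions_from_flow()] and
#'   [dedupe_channel_triggers()]).
#' @param variant `"wave_wise"` or `"channel_wise"`.
#' @param annotation_keys names of recording annotations to copy in.
#' @param rec the source [grid_recording()] (required if `annotation_keys`
#'   given).
#' @param cap velocity cap for reported/aggregated distributions, mm/s.
#' @return a tibble (class `characterization_table`) with attribute
#'   `"units"` naming each measure's unit.
#' @export
emit_table <- function(ws, variant = c("wave_wise", "channel_wise"),
                       annotation_keys = character(), rec = NULL, cap = 120) {
  variant <- match.arg(variant)
  chan <- channel_measures(ws, cap)
  chan$spatial_scale <- attr(ws, "spatial_scale")
  tab <- if (variant == "wave_wise") {
    wave_measures(chan, cap)
  } else {
    dplyr::select(chan, -"spatial_scale")
  }
  if (length(annotation_keys)) {
    if (is.null(rec)) stop("rec is required to propagate annotations")
    missing_keys <- setdiff(annotation_keys, names(rec$annotations))
    if (length(missing_keys)) {
      stop("unknown annotation key(s): ", paste(missing_keys, collapse = ", "),
           "; available: ", paste(names(rec$annotations), collapse = ", "))
    }
    for (key in annotation_keys) tab[[key]] <- rec$annotations[[key]]
  }
  attr(tab, "units") <- c(velocity = "mm/s", velocity_plane_fit = "mm/s",
                          direction = "rad", planarity = "",
                          interwave_interval = "s", onset = "s", delay = "s")
  attr(tab, "variant") <- variant
  class(tab) <- c("characterization_table", class(tab))
  tab
}

#' Write a characterization table with a units/provenance sidecar
#'
#' @param tab a `characterization_table`.
#' @param path CSV output path; a JSON sidecar `<path>.json` records column
#'   units and the wave-detection parameters.
#' @param params extra provenance to embed in the sidecar.
#' @return `path`, invisibly.
#' @export
write_characterization <- function(tab, path, params = list()) {
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE)
  side <- list(units = as.list(attr(tab, "units")),
               variant = attr(tab, "variant"),
               params = params)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
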