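#' Broom-style tidiers
#'
#' `tidy()` turns pipeline objects into plain tibbles; `glance()` gives a
#' one-row summary.
#'
#' @param x a package object.
#' @param ... unused.
#' @name tidiers
NULL

#' @rdname tidiers
#' @exportS3Method generics::tidy
tidy.wave_delay_map <- function(x, ...) {
  idx <- expand.grid(y = seq_len(nrow(x$T)), x = seq_len(ncol(x$T)))
  tibble::tibble(x = idx$x - 1L, y = idx$y - 1L,
                 delay = x$T[cbind(idx$y, idx$x)])
}

#' @rdname tidiers
#' @exportS3Method generics::tidy
tidy.flow_field <- function(x, ...) {
  d <- dim(x$u)
  idx <- expand.grid(frame = seq_len(d[1]), y = seq_len(d[2]),
                     x = seq_len(d[3]))
  tibble::tibble(frame = idx$frame, x = idx$x - 1L, y = idx$y - 1L,
                 u = x$u[as.matrix(idx)], v = x$v[as.matrix(idx)])
}

#' @rdname tidiers
#' @exportS3Method generics::glance
glance.wave_set <- function(x, ...) {
  real <- x$wave[x$wave != NOISE_LABEL]
  tibble::tibble(
    n_waves = length(unique(real)),
    n_triggers = nrow(x),
    n_noise = sum(x$wave == NOISE_LABEL),
    time_space_ratio = attr(x, "params")$time_space_ratio %||% NA_real_,
    neighbour_distance = attr(x, "params")$neighbour_distance %||% NA_real_,
    min_samples_per_wave = attr(x, "params")$min_samples_per_wave %||% NA_real_
  )
}

#' @rdname tidiers
#' @exportS3Method generics::glance
glance.trigger_set <- function(x, ...) {
  tibble::tibble(
    detector = attr(x, "detector"),
    n_up = sum(x$state == "up"),
    n_down = sum(x$state == "down"),
    n_channels = length(unique(x$channel))
  )
}

#' @rdname tidiers
#' @exportS3Method generics::glance
glance.characterization_table <- function(x, ...) {
  tibble::tibble(
    variant = attr(x, "variant"),
    n_rows = nrow(x),
    n_waves = length(unique(x$wave)),
    median_velocity = stats::median(x$velocity, na.rm = TRUE),
    median_planarity = if ("planarity" %in% names(x)) {
      stats::median(x$planarity, na.rm = TRUE)
    } else NA_real_
  )
}
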