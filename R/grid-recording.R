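#' Grid recording container
#'
#' A `grid_recording` holds a set of channels (electrodes or imaging pixels)
#' arranged on a rectangular integer-coordinate grid, each carrying a real
#' time series sampled at a common rate. It is the object every pipeline
#' stage consumes and returns.
#'
#' @param signals numeric matrix, `n_channels x n_samples`; one row per
#'   occupied grid site.
#' @param coords data frame / tibble with integer columns `x`, `y`
#'   (0-based grid positions), one row per channel, unique.
#' @param sampling_rate sampling rate in Hz, strictly positive.
#' @param spatial_scale inter-site spacing in mm, strictly positive.
#' @param t_start time of the first sample in seconds (default 0).
#' @param units signal units label (e.g. `"uV"`, `"dF/F"`, `"z"`).
#' @param annotations named list of free-form metadata (anesthetic, dose,
#'   dataset id, ...), propagated into characterization tables on request.
#' @param channel_mask optional logical vector over channels; `FALSE` marks a
#'   site as empty (kept in place, never renumbered).
#'
#' @details
#' Grid coordinates are 0-based; `x` increases rightward and `y` upward.
#' Unoccupied grid sites are representable either as masked channels or as
#' absent rows; helpers that rasterize onto the full `n_x x n_y` grid insert
#' `NA` at absent sites. Times are seconds, distances mm, velocities mm/s
#' throughout the package; unit conversion belongs at I/O boundaries.
#'
#' Every processing block appends one record to the recording's processing
#' history (`attr(rec, "history")`), so any artifact can be traced to the
#' exact block sequence and parameters that produced it.
#'
#' @return An object of class `grid_recording`.
#' @examples
#' rec <- grid_recording(matrix(rnorm(4 * 100), 4),
#'                       coords = expand.grid(x = 0:1, y = 0:1),
#'                       sampling_rate = 25, spatial_scale = 0.05)
#' rec
#' @export
grid_recording <- function(signals, coords, sampling_rate, spatial_scale,
                           t_start = 0, units = "a.u.",
                           annotations = list(), channel_mask = NULL) {
  signals <- as.matrix(signals)
  storage.mode(signals) <- "double"
  coords <- tibble::as_tibble(coords[, c("x", "y")])
  coords$x <- as.integer(coords$x)
  coords$y <- as.integer(coords$y)
  if (is.null(channel_mask)) channel_mask <- rep(TRUE, nrow(signals))
  structure(
    list(
      signals = signals,
      coords = coords,
      sampling_rate = as.numeric(sampling_rate),
      spatial_scale = as.numeric(spatial_scale),
      t_start = as.numeric(t_start),
      units = units,
      annotations = annotations,
      channel_mask = channel_mask
    ),
    history = list(),
    class = "grid_recording"
  )
}

#' @export
print.grid_recording <- function(x, ...) {
  cat(sprintf(
    "<grid_recording> %d channels (%d active) on %dx%d grid\n",
    n_channels(x), sum(x$channel_mask), grid_dims(x)[1], grid_dims(x)[2]
  ))
  cat(sprintf(
    "  %d samples @ %g Hz (%.2f s), spacing %g mm, units '%s'\n",
    n_samples(x), x$sampling_rate, n_samples(x) / x$sampling_rate,
    x$spatial_scale, x$units
  ))
  if (length(attr(x, "history"))) {
    blocks <- vapply(attr(x, "history"), `[[`, "", "block")
    cat("  history:", paste(blocks, collapse = " -> "), "\n")
  }
  invisible(x)
}

#' @rdname grid_recording
#' @param rec a `grid_recording`.
#' @export
n_channels <- function(rec) nrow(rec$signals)

#' @rdname grid_recording
#' @export
n_samples <- function(rec) ncol(rec$signals)

#' @rdname grid_recording
#' @export
grid_dims <- function(rec) c(max(rec$coords$x) + 1L, max(rec$coords$y) + 1L)

#' Sample times of a recording
#' @param rec a `grid_recording`.
#' @return numeric vector of length `n_samples(rec)`, in seconds.
#' @export
sample_times <- function(rec) {
  rec$t_start + (seq_len(n_samples(rec)) - 1) / rec$sampling_rate
}

#' Append one processing-history record
#'
#' History is append-only: each stage/block run records its name and full
#' parameter set on the recording it returns.
#'
#' @param rec a `grid_recording`.
#' @param block block name.
#' @param params named list of the parameters the block ran with.
#' @return the recording with one more history entry.
#' @export
append_history <- function(rec, block, params = list()) {
  h <- attr(rec, "history")
  h[[length(h) + 1L]] <- list(block = block, params = params)
  attr(rec, "history") <- h
  rec
}

#' @rdname append_history
#' @export
recording_history <- function(rec) attr(rec, "history")

#' Validate a grid recording against its invariants
#'
#' The stage-entry check: verifies metadata presence and positivity,
#' coordinate uniqueness and rectangularity (0-based integer coordinates
#' inside the bounding grid), consistent signal dimensions, and that no
#' active channel is all-NaN. Returns a report; never throws and never
#' mutates the recording.
#'
#' @param rec object to check.
#' @return A tibble with columns `check` and `message` listing violated
#'   invariants (zero rows = pass), with attribute `"pass"`.
#' @examples
#' rec <- grid_recording(matrix(0, 2, 5), data.frame(x = c(0L, 0L), y = c(0L, 0L)),
#'                       25, 0.05)
#' check_input(rec)
#' @export
check_input <- function(rec) {
  bad <- list()
  note <- function(check, message) {
    bad[[length(bad) + 1L]] <<- tibble::tibble(check = check, message = message)
  }
  if (!inherits(rec, "grid_recording")) {
    note("class", "not a grid_recording")
  } else {
    for (f in c("signals", "coords", "sampling_rate", "spatial_scale", "t_start")) {
      if (is.null(rec[[f]])) note("metadata", paste("missing metadata:", f))
    }
    if (!is.null(rec$sampling_rate) &&
        (!is.finite(rec$sampling_rate) || rec$sampling_rate <= 0)) {
      note("sampling_rate", "sampling_rate must be > 0")
    }
    if (!is.null(rec$spatial_scale) &&
        (!is.finite(rec$spatial_scale) || rec$spatial_scale <= 0)) {
      note("spatial_scale", "spatial_scale must be > 0")
    }
    if (!is.null(rec$coords)) {
      if (anyDuplicated(rec$coords[, c("x", "y")])) {
        note("coords", "coords not unique")
      }
      if (any(rec$coords$x < 0L) || any(rec$coords$y < 0L)) {
        note("coords", "coords must be non-negative integers")
      }
    }
    if (!is.null(rec$signals) && !is.null(rec$coords) &&
        nrow(rec$signals) != nrow(rec$coords)) {
      note("shape", "signals rows and coords rows differ")
    }
    if (!is.null(rec$signals)) {
      allnan <- apply(rec$signals, 1L, function(s) all(is.na(s)))
      if (any(allnan & rec$channel_mask)) {
        note("signals", sprintf("%d active channel(s) are all-NaN", sum(allnan & rec$channel_mask)))
      }
    }
  }
  report <- if (length(bad)) dplyr::bind_rows(bad) else {
    tibble::tibble(check = character(), message = character())
  }
  attr(report, "pass") <- nrow(report) == 0L
  report
}

#' Rasterize per-channel values onto the full grid
#'
#' @param rec a `grid_recording` supplying coords and grid dimensions.
#' @param values numeric vector, one per channel.
#' @return `n_y x n_x` matrix (row = y, column = x), `NA` at empty sites.
#' @keywords internal
rasterize <- function(rec, values) {
  d <- grid_dims(rec)
  m <- matrix(NA_real_, nrow = d[2], ncol = d[1])
  keep <- rec$channel_mask
  m[cbind(rec$coords$y[keep] + 1L, rec$coords$x[keep] + 1L)] <- values[keep]
  m
}

#' @exportS3Method tibble::as_tibble
as_tibble.grid_recording <- function(x, ...) {
  tt <- sample_times(x)
  purrr::map_dfr(seq_len(n_channels(x)), function(i) {
    tibble::tibble(
      channel = i, x = x$coords$x[i], y = x$coords$y[i],
      time = tt, value = x$signals[i, ]
    )
  })
}
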