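#' Read and write grid recordings
#'
#' Recordings are stored as a "csv-bundle": a directory holding
#' `signals.csv` (wide, one column per channel, one row per sample),
#' `channels.csv` (columns `channel`, `x`, `y`, `active`) and `meta.yaml`
#' (sampling rate, spatial scale, start time, units, annotations and the
#' processing history). Write followed by read is the identity on
#' coordinates and metadata and preserves signals to float precision.
#'
#' @param path directory of the bundle.
#' @param format storage format; only `"csv-bundle"` is supported.
#' @return `read_recording()` returns a `grid_recording`;
#'   `write_recording()` returns `path` invisibly.
#' @examples
#' rec <- simulate_wave_recording(n_x = 4, n_y = 4, n_waves = 1, seed = 1)$recording
#' p <- file.path(tempdir(), "rec-bundle")
#' write_recording(rec, p)
#' rec2 <- read_recording(p)
#' all.equal(rec$signals, rec2$signals)
#' @export
read_recording <- function(path, format = "csv-bundle") {
  format <- match.arg(format)
  meta_path <- file.path(path, "meta.yaml")
  if (!file.exists(meta_path)) stop("missing metadata: meta.yaml not found in ", path)
  meta <- yaml::read_yaml(meta_path)
  for (key in c("sampling_rate", "spatial_scale")) {
    if (is.null(meta[[key]])) stop("missing metadata: ", key)
  }
  channels <- utils::read.csv(file.path(path, "channels.csv"))
  signals <- as.matrix(utils::read.csv(file.path(path, "signals.csv")))
  rec <- grid_recording(
    signals = t(signals),
    coords = channels[, c("x", "y")],
    sampling_rate = meta$sampling_rate,
    spatial_scale = meta$spatial_scale,
    t_start = meta$t_start %||% 0,
    units = meta$units %||% "a.u.",
    annotations = meta$annotations %||% list(),
    channel_mask = if (!is.null(channels$active)) as.logical(channels$active) else NULL
  )
  attr(rec, "history") <- meta$history %||% list()
  rec
}

#' @rdname read_recording
#' @param rec a `grid_recording`.
#' @export
write_recording <- function(rec, path, format = "csv-bundle") {
  format <- match.arg(format)
  stopifnot(inherits(rec, "grid_recording"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  sig <- t(rec$signals)
  colnames(sig) <- sprintf("ch%03d", seq_len(n_channels(rec)))
  utils::write.csv(sig, file.path(path, "signals.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(channel = seq_len(n_channels(rec)),
               x = rec$coords$x, y = rec$coords$y,
               active = rec$channel_mask),
    file.path(path, "channels.csv"), row.names = FALSE
  )
  meta <- list(
    sampling_rate = rec$sampling_rate,
    spatial_scale = rec$spatial_scale,
    t_start = rec$t_start,
    units = rec$units,
    annotations = rec$annotations,
    history = recording_history(rec)
  )
  yaml::write_yaml(meta, file.path(path, "meta.yaml"))
  invisible(path)
}

#' Read/write trigger and wave tables
#'
#' Triggers and wave labelings are plain tidy tables; these helpers attach
#' and restore the attributes (source parameters) carried alongside.
#'
#' @param x a tibble as returned by a trigger detector or
#'   [cluster_triggers_to_waves()].
#' @param path CSV file path.
#' @return `read_triggers()` a tibble; `write_triggers()` `path`, invisibly.
#' @export
write_triggers <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_triggers
#' @export
read_triggers <- function(path) tibble::as_tibble(utils::read.csv(path))

`%||%` <- function(a, b) if (is.null(a)) b else a
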