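#' Resolve a stage config file from a profile name
#'
#' Profiles name calibration presets hierarchically with underscores
#' (`data1_subject3`) and optional '|'-separated variations
#' (`data1_subject3|methodA`). Lookup, per stage: try
#' `config_<profile>.yaml`; if absent, strip the last underscore-separated
#' subcategory and retry, down to the bare name. A variation suffix is kept
#' through that loop (`config_data1|methodA.yaml`, `config|methodA.yaml`,
#' ...); only when the bare variation file is also absent is the variation
#' dropped and the stripping loop restarted, ending at the default
#' `config.yaml`. Because '|' is awkward in file names, `@` is accepted as
#' an equivalent spelling (`config_data1@methodA.yaml`).
#'
#' @param profile profile string (may be `NULL`/empty for the default).
#' @param files character vector of available config file names.
#' @return the chosen file name (as it appears in `files`).
#' @examples
#' resolve_config("data1_subject3", c("config_data1.yaml", "config.yaml"))
#' @export
resolve_config <- function(profile, files) {
  candidates <- config_candidates(profile)
  for (cand in candidates) {
    hit <- files[files %in% variation_spellings(cand)]
    if (length(hit)) return(hit[1])
  }
  stop("no config found and no default config.yaml present")
}

# ordered candidate list implementing the lookup rules
config_candidates <- function(profile) {
  profile <- if (is.null(profile)) "" else profile
  parts <- strsplit(profile, "|", fixed = TRUE)[[1]]
  base <- if (length(parts)) parts[1] else ""
  variation <- if (length(parts) > 1) parts[2] else NULL
  strip_seq <- function(b) {
    out <- character(0)
    while (nzchar(b)) {
      out <- c(out, b)
      b <- sub("_[^_]*$", "", b)
      if (b == utils::tail(out, 1)) break   # no underscore left
    }
    out
  }
  bases <- strip_seq(base)
  cands <- character(0)
  if (!is.null(variation)) {
    cands <- c(
      paste0("config_", bases, "|", variation, ".yaml"),
      paste0("config|", variation, ".yaml")
    )
  }
  c(cands, paste0("config_", bases, ".yaml"), "config.yaml")
}

variation_spellings <- function(name) c(name, gsub("|", "@", name, fixed = TRUE))

read_stage_config <- function(configs_dir, stage, profile) {
  dir <- file.path(configs_dir, stage)
  files <- list.files(dir)
  chosen <- resolve_config(profile, files)
  cfg <- yaml::read_yaml(file.path(dir, chosen))
  attr(cfg, "file") <- file.path(dir, chosen)
  cfg
}

merge_params <- function(cfg, global) {
  for (key in names(global)) cfg[[key]] <- global[[key]]
  cfg
}

save_plot <- function(p, path, fmt = "png") {
  tryCatch(
    suppressMessages(ggplot2::ggsave(paste0(path, ".", fmt), p,
                                     width = 6, height = 4, dpi = 120)),
    error = function(e) warning("QC plot failed: ", conditionMessage(e))
  )
}

stage_log <- function(dir, stage, cfg, elapsed) {
  jsonlite::write_json(
    list(stage = stage, config_file = attr(cfg, "file"),
         params = cfg[setdiff(names(cfg), "")],
         elapsed_s = round(elapsed, 3),
         package_version = as.character(utils::packageVersion("wavescan")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    file.path(dir, paste0(stage, "_log.json")), auto_unbox = TRUE,
    pretty = TRUE
  )
}

#' Run the full pipeline from config files
#'
#' Executes the configured stages in order — data entry/simulation,
#' processing (any ordered block combination), trigger detection (one
#' method), wave detection (clustering, optionally optical flow and mode
#' clustering), and characterization — writing each stage's output, a JSON
#' log of its parameters, and optional QC plots under `out_dir`. Parameters
#' in the top-level config's `global` section override identically named
#' stage parameters. Stages whose outputs are newer than their config are
#' skipped on rerun (`force = TRUE` disables caching); deterministic stages
#' rerun bit-identically for a fixed config and seed.
#'
#' @param configs_dir directory with `pipeline.yaml` and one subdirectory
#'   of config files per stage.
#' @param profile calibration profile (see [resolve_config()]).
#' @param out_dir output directory.
#' @param force rerun even if cached outputs are up to date.
#' @return invisibly, a list with the final `table`, the wave tibble
#'   `waves`, per-stage output paths and the resolved configs.
#' @export
run_pipeline <- function(configs_dir, profile = NULL, out_dir, force = FALSE) {
  top <- yaml::read_yaml(file.path(configs_dir, "pipeline.yaml"))
  global <- top$global %||% list()
  plots_on <- !isFALSE(global$plots)
  fmt <- global$plot_format %||% "png"
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  state <- list()
  paths <- list()
  configs <- list()

  fresh <- function(out_file, cfg) {
    !force && file.exists(out_file) &&
      file.mtime(out_file) >= file.mtime(attr(cfg, "file"))
  }

  for (stage in top$stages) {
    cfg <- merge_params(read_stage_config(configs_dir, stage, profile), global)
    configs[[stage]] <- cfg
    sdir <- file.path(out_dir, stage)
    dir.create(sdir, showWarnings = FALSE)
    t0 <- proc.time()[["elapsed"]]

    if (stage == "simulate") {
      bundle <- file.path(sdir, "recording")
      if (fresh(file.path(bundle, "meta.yaml"), cfg) && !is.null(state$rec)) {
        # cached
      } else {
        sim <- if ((cfg$kind %||% "calcium") == "mua") {
          do.call(simulate_mua_recording,
                  cfg[intersect(names(cfg), names(formals(simulate_mua_recording)))])
        } else {
          do.call(simulate_wave_recording,
                  cfg[intersect(names(cfg), names(formals(simulate_wave_recording)))])
        }
        write_recording(sim$recording, bundle)
        write_triggers(sim$truth, file.path(sdir, "truth.csv"))
        state$rec <- sim$recording
        state$truth <- sim$truth
      }
      paths$recording <- bundle
    } else if (stage == "data_entry") {
      state$rec <- read_recording(cfg$input)
      rep <- check_input(state$rec)
      if (!attr(rep, "pass")) {
        stop("stage data_entry: input check failed: ",
             paste(rep$message, collapse = "; "))
      }
      paths$recording <- cfg$input
    } else if (stage == "process") {
      rec <- state$rec
      for (blk in cfg$blocks) {
        fn_name <- blk$name
        fn <- match.fun(fn_name)
        args <- c(list(rec), blk[setdiff(names(blk), "name")])
        rec <- tryCatch(do.call(fn, args), error = function(e) {
          stop("stage process, block '", fn_name, "' failed with params ",
               jsonlite::toJSON(blk, auto_unbox = TRUE), ": ",
               conditionMessage(e))
        })
      }
      state$rec <- rec
      bundle <- file.path(sdir, "processed")
      write_recording(rec, bundle)
      paths$processed <- bundle
      if (plots_on) save_plot(plot_traces(rec), file.path(sdir, "traces"), fmt)
    } else if (stage == "triggers") {
      method <- cfg$method %||% "hilbert"
      ts <- switch(method,
        hilbert = detect_hilbert_triggers(
          state$rec, phase_threshold = cfg$phase_threshold %||% -pi / 2),
        minima = detect_minima_triggers(
          state$rec, window = cfg$window %||% 2,
          rel_threshold = cfg$rel_threshold %||% 0.5,
          min_peak_distance = cfg$min_peak_distance %||% 1,
          rise_interval = cfg$rise_interval %||% 0.1),
        threshold = {
          t0s <- detect_threshold_triggers(
            state$rec, method = cfg$threshold_method %||% "bimodal_fit",
            fixed_value = cfg$fixed_value, sigma_factor = cfg$sigma_factor %||% 3)
          filter_min_state_durations(t0s, cfg$min_up %||% 0, cfg$min_down %||% 0)
        },
        stop("stage triggers: unknown method '", method, "'")
      )
      state$triggers <- ts
      write_triggers(ts, file.path(sdir, "triggers.csv"))
      paths$triggers <- file.path(sdir, "triggers.csv")
      if (plots_on) {
        save_plot(plot_traces(state$rec, ts), file.path(sdir, "triggers"), fmt)
      }
    } else if (stage == "waves") {
      ratio <- cfg$time_space_ratio %||% compute_time_space_ratio(
        cfg$v0 %||% 15, state$rec$sampling_rate, state$rec$spatial_scale)
      ws <- cluster_triggers_to_waves(
        state$triggers, ratio,
        neighbour_distance = cfg$neighbour_distance %||% 3,
        min_samples_per_wave = cfg$min_samples_per_wave %||% 10) |>
        dedupe_channel_triggers()
      if (isTRUE(cfg$flow %||% TRUE)) {
        fld <- phase_field(state$rec)
        flow <- compute_optical_flow(fld, alpha = cfg$alpha %||% 1.5)
        ws <- wave_directions_from_flow(ws, flow)
        state$flow <- flow
      }
      if (!is.null(cfg$modes)) ws <- cluster_wave_modes(ws, cfg$modes,
                                                        seed = cfg$seed %||% 0)
      state$waves <- ws
      write_triggers(ws, file.path(sdir, "waves.csv"))
      paths$waves <- file.path(sdir, "waves.csv")
      if (plots_on && nrow(ws)) {
        wid <- ws$wave[ws$wave != NOISE_LABEL][1]
        if (!is.na(wid)) {
          save_plot(plot_delay_map(build_delay_map(ws, wid), ws),
                    file.path(sdir, "delay_map"), fmt)
        } else {
          warning("empty wave set; skipping delay-map plot")
        }
      }
    } else if (stage == "characterize") {
      tab <- emit_table(state$waves,
                        variant = cfg$variant %||% "channel_wise",
                        annotation_keys = cfg$annotations %||% character(),
                        rec = state$rec, cap = cfg$cap %||% 120)
      state$table <- tab
      out_csv <- file.path(sdir, "characterization.csv")
      write_characterization(tab, out_csv,
                             params = attr(state$waves, "params"))
      paths$table <- out_csv
      if (plots_on) save_plot(plot_measures(tab), file.path(sdir, "measures"), fmt)
    } else {
      stop("unknown stage '", stage, "'")
    }
    stage_log(sdir, stage, cfg, proc.time()[["elapsed"]] - t0)
  }
  invisible(list(table = state$table, waves = state$waves,
                 paths = paths, configs = configs))
}
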