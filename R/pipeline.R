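# Config-driven experiment runner: drive construction, simulation,
# quantification, reproducible output bundles, sweeps, fixtures.

# Resolve the drive block of a config into a drive_trace.
.build_drive <- function(cfg) {
  if (!is.null(cfg$drive$spec)) {
    s <- cfg$drive$spec
    spec <- oscillation_spec(baseline = s$baseline_M, peak = s$peak_M,
                             period = s$period_s,
                             spike_width = s$spike_width_s,
                             n_spikes = s$n_spikes,
                             duration = s$duration_s,
                             desens_decay = s$desens_decay,
                             jitter_sd = s$jitter_sd_s,
                             noise_sd = s$noise_sd, seed = cfg$seed,
                             onset_time = s$onset_time_s, dt = s$dt_s,
                             shape = s$shape)
    generate_oscillating_drive(spec)
  } else {
    resc <- cfg$drive$csv$rescale
    if (is.null(resc)) {
      read_drive_csv(cfg$drive$csv$path)
    } else {
      df <- utils::read.csv(cfg$drive$csv$path, fileEncoding = "UTF-8")
      if (!all(c("time_s", "ratio") %in% names(df))) {
        stop("ratio CSV must have columns time_s, ratio", call. = FALSE)
      }
      scale_ratio_log(ratio_trace(df$time_s, df$ratio),
                      low = resc$low_M, high = resc$high_M)
    }
  }
}

#' Run a configured experiment end to end
#'
#' Validates the config, builds the cytosolic drive (generator or CSV),
#' simulates the matrix trajectory, quantifies the oscillations and
#' writes a result bundle to `cfg$output_dir`: `drive.csv`,
#' `trajectory.csv`, `summary.json` and `run.log`. All outputs are
#' written atomically; `summary.json` is deterministic given config and
#' seed (byte-identical on rerun).
#'
#' @param cfg A config list ([default_config()], [preset_config()]) or a
#'   path to a JSON/YAML config file.
#' @param write Logical; write the bundle (default) or just return it.
#' @return Invisibly, a list with elements `drive`, `trajectory`,
#'   `summary` (an `oscillation_summary`), `summary_json` (the list
#'   serialised to summary.json) and `paths`.
#' @examples
#' \donttest{
#' res <- run_experiment(preset_config("bulk"), write = FALSE)
#' res$summary
#' }
#' @export
run_experiment <- function(cfg, write = TRUE) {
  if (is.character(cfg)) cfg <- read_config(cfg)
  validate_config(cfg)
  obj <- .config_objects(cfg)
  set.seed(cfg$seed)

  drive <- .build_drive(cfg)
  traj <- simulate_matrix(drive, obj$membrane, obj$exchanger,
                          obj$simulation,
                          na_mito = cfg$simulation$na_mito_M,
                          na_cyt = cfg$simulation$na_cyt_M)
  an <- cfg$analysis
  summary <- summarize_oscillations(traj$time_s, traj$ca_free_M,
                                    onset = an$onset_s,
                                    prominence_fraction =
                                      an$prominence_fraction,
                                    bin_width = an$bin_width_s,
                                    n_bins = an$n_bins,
                                    event_time = an$event_time_s,
                                    trajectory = traj)

  # the hash identifies the experiment, not where its outputs land
  hash <- .config_hash(cfg[setdiff(names(cfg), "output_dir")])
  sj <- list(
    schema_version = "1",
    preset = if (is.null(cfg$preset)) NA else cfg$preset,
    seed = cfg$seed,
    config_hash = hash,
    n_peaks = nrow(summary$peaks),
    bin_counts = as.integer(summary$bin_counts),
    ignored_peaks = attr(summary$bin_counts, "ignored"),
    amplitude_series_M = summary$amplitude_series,
    mean_amplitude_M = if (length(summary$amplitude_series))
      mean(summary$amplitude_series) else 0,
    decay_half_time_s = if (is.null(summary$decay_half_time)) NULL
      else as.numeric(summary$decay_half_time),
    reverse_fraction = reverse_mode_fraction(traj),
    n_mode_segments = if (is.null(summary$mode_segments)) 0L
      else nrow(summary$mode_segments),
    prominence_threshold_M = summary$parameters$prominence_threshold
  )

  paths <- NULL
  if (write) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      drive = file.path(cfg$output_dir, "drive.csv"),
      trajectory = file.path(cfg$output_dir, "trajectory.csv"),
      summary = file.path(cfg$output_dir, "summary.json"),
      log = file.path(cfg$output_dir, "run.log"))
    write_drive_csv(drive, paths$drive)
    write_trajectory_csv(traj, paths$trajectory)
    .write_atomic(paths$summary, function(p) {
      jsonlite::write_json(sj, p, auto_unbox = TRUE, digits = NA,
                           null = "null", pretty = TRUE)
    })
    solver <- attr(traj, "solver")
    .write_atomic(paths$log, function(p) {
      writeLines(c(
        sprintf("mitoncx %s",
                as.character(utils::packageVersion("mitoncx"))),
        sprintf("run at %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
        sprintf("preset: %s",
                if (is.null(cfg$preset)) "(none)" else cfg$preset),
        sprintf("seed: %d", cfg$seed),
        sprintf("config hash: %s", hash),
        sprintf("solver steps: %d, rhs evaluations: %d",
                solver$steps, solver$rhs_evals),
        sprintf("samples: %d, peaks: %d", nrow(traj),
                nrow(summary$peaks))), p)
    })
  }
  invisible(list(drive = drive, trajectory = traj, summary = summary,
                 summary_json = sj, paths = paths))
}

#' Sweep one simulation parameter across an experiment
#'
#' Reruns the configured experiment for each value of `param`
#' (`"n_ncx"` or `"buffering_factor"`), quantifying each run. Writes
#' `sweep.csv` to the output directory unless `write = FALSE`.
#'
#' @param cfg Config list or path, as for [run_experiment()].
#' @param param `"n_ncx"` or `"buffering_factor"`.
#' @param values Nonempty numeric vector of sweep values.
#' @param write Write `sweep.csv`?
#' @return Data frame with columns `value`, `peak_count`,
#'   `mean_amplitude_M`, `reverse_fraction`.
#' @export
run_sweep <- function(cfg, param = c("n_ncx", "buffering_factor"),
                      values, write = TRUE) {
  param <- match.arg(param)
  if (missing(values) || length(values) == 0L) {
    stop("`values` must be a nonempty vector", call. = FALSE)
  }
  if (is.character(cfg)) cfg <- read_config(cfg)
  validate_config(cfg)
  rows <- lapply(values, function(v) {
    cfg_v <- cfg
    cfg_v$simulation[[param]] <- v
    res <- run_experiment(cfg_v, write = FALSE)
    data.frame(value = v,
               peak_count = res$summary_json$n_peaks,
               mean_amplitude_M = res$summary_json$mean_amplitude_M,
               reverse_fraction = res$summary_json$reverse_fraction)
  })
  out <- do.call(rbind, rows)
  if (write) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    .write_atomic(file.path(cfg$output_dir, "sweep.csv"), function(p) {
      utils::write.csv(out, p, row.names = FALSE, fileEncoding = "UTF-8")
    })
  }
  out
}

#' Write the standard synthetic test traces
#'
#' Four fixed-seed drive CSVs -- oscillating trains rescaled to 1.5 uM
#' and 15 uM, a BAPTA-style washout step and a flat baseline trace --
#' plus `manifest.json` recording generator settings and MD5 checksums.
#'
#' @param output_dir Writable directory (created if needed).
#' @param seed Generator seed. Default 1.
#' @return Invisibly, the manifest list.
#' @export
make_fixtures <- function(output_dir, seed = 1L) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(seed)
  traces <- list(
    drive_osc_1p5uM = generate_oscillating_drive(
      oscillation_spec(peak = 1.5e-6, seed = seed)),
    drive_osc_15uM = generate_oscillating_drive(
      oscillation_spec(peak = 1.5e-5, seed = seed)),
    drive_washout = generate_washout_drive(2e-7, 1e-8, switch_time = 300,
                                           duration = 600),
    drive_flat = generate_oscillating_drive(
      oscillation_spec(n_spikes = 0L, duration = 600, seed = seed))
  )
  files <- character(0)
  for (nm in names(traces)) {
    f <- file.path(output_dir, paste0(nm, ".csv"))
    write_drive_csv(traces[[nm]], f)
    files[nm] <- f
  }
  manifest <- list(
    seed = seed,
    files = lapply(names(files), function(nm) {
      list(name = basename(files[[nm]]),
           md5 = unname(tools::md5sum(files[[nm]])),
           n_samples = nrow(traces[[nm]]))
    })
  )
  .write_atomic(file.path(output_dir, "manifest.json"), function(p) {
    jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  })
  invisible(manifest)
}
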