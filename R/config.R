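# Experiment configuration: defaults, presets, schema validation,
# JSON/YAML loading.

#' Default experiment configuration
#'
#' Nested list with blocks `geometry`, `exchanger`, `simulation`, `drive`
#' and `analysis` plus top-level `seed`, `output_dir` and `preset`. All
#' quantities are SI (molar, volts, kelvin, seconds, litres); key names
#' carry the unit suffix. Exactly one drive source must be set: either
#' `drive$spec` (generator parameters) or `drive$csv` (path plus optional
#' logarithmic rescale block).
#'
#' @param ... Named top-level overrides merged over the defaults.
#' @return A config list (schema-valid).
#' @examples
#' cfg <- default_config(seed = 7)
#' validate_config(cfg)
#' @export
default_config <- function(...) {
  cfg <- list(
    preset = NULL,
    seed = 1L,
    output_dir = ".",
    geometry = list(cyl_length_um = 1, radius_um = 0.5),
    exchanger = list(n_na = 3L,
                     k_turnover = formals(exchanger_params)$k_turnover,
                     k_ca_M = 1e-5, k_na_M = 8e-3,
                     activation_enabled = FALSE,
                     k_act_M = 5e-8, h_act = 4),
    simulation = list(n_ncx = 100L, buffering_factor = 100,
                      v_mito_L = NULL, v_m_V = -0.02, temperature_K = 298,
                      na_mito_M = 4.54e-3, na_cyt_M = 10e-3,
                      rel_tol = 1e-10, abs_tol = 1e-14, max_step_s = Inf,
                      init_free_M = NULL, null_tol_ions_s = 1),
    drive = list(spec = list(baseline_M = 1e-7, peak_M = 1.5e-6,
                             period_s = 50, spike_width_s = 20,
                             n_spikes = NULL, duration_s = 600,
                             desens_decay = 0.05, jitter_sd_s = 0,
                             noise_sd = 0, onset_time_s = 0, dt_s = 0.5,
                             shape = "cosine"),
                 csv = NULL),
    analysis = list(onset_s = 0, prominence_fraction = 0.2,
                    bin_width_s = 200, n_bins = 3L,
                    event_time_s = NULL)
  )
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  cfg
}

#' Preset configurations for the standard simulation scenarios
#'
#' * `"bulk"`: measured bulk cytosolic amplitude (1.5 uM spikes), 100
#'   exchangers, buffering 100, -20 mV, gate off. Small matrix
#'   oscillations.
#' * `"microdomain"`: microdomain amplitude (15 uM spikes), buffering 1000.
#'   Larger matrix oscillations.
#' * `"energised"`: -180 mV membrane potential; the reversal point sits
#'   so low that the exchanger stays out of effective reverse mode.
#' * `"ionomycin_trigger"`: matrix-Ca2+ activation gate on with a small
#'   matrix preload (free Ca2+ just above the gate half-point),
#'   emulating rescue of oscillations by low-dose ionomycin; the same
#'   configuration without the preload yields no oscillations.
#'
#' @param name Preset name.
#' @param seed Seed recorded in the config.
#' @return A config list.
#' @export
preset_config <- function(name = c("bulk", "microdomain", "energised",
                                   "ionomycin_trigger"),
                          seed = 1L) {
  name <- match.arg(name)
  cfg <- default_config(seed = as.integer(seed), preset = name)
  if (name == "microdomain") {
    cfg$drive$spec$peak_M <- 1.5e-5
    cfg$simulation$buffering_factor <- 1000
  } else if (name == "energised") {
    cfg$drive$spec$peak_M <- 1.5e-5
    cfg$simulation$v_m_V <- -0.18
  } else if (name == "ionomycin_trigger") {
    cfg$drive$spec$peak_M <- 1.5e-5
    cfg$exchanger$activation_enabled <- TRUE
    cfg$simulation$init_free_M <- 8e-8
  }
  cfg
}

# allowed keys per block (schema); NULL-able keys listed too
.CONFIG_SCHEMA <- list(
  top = c("preset", "seed", "output_dir", "geometry", "exchanger",
          "simulation", "drive", "analysis"),
  geometry = c("cyl_length_um", "radius_um"),
  exchanger = c("n_na", "k_turnover", "k_ca_M", "k_na_M",
                "activation_enabled", "k_act_M", "h_act"),
  simulation = c("n_ncx", "buffering_factor", "v_mito_L", "v_m_V",
                 "temperature_K", "na_mito_M", "na_cyt_M", "rel_tol",
                 "abs_tol", "max_step_s", "init_free_M",
                 "null_tol_ions_s"),
  drive = c("spec", "csv"),
  drive_spec = c("baseline_M", "peak_M", "period_s", "spike_width_s",
                 "n_spikes", "duration_s", "desens_decay", "jitter_sd_s",
                 "noise_sd", "onset_time_s", "dt_s", "shape"),
  drive_csv = c("path", "rescale"),
  drive_rescale = c("low_M", "high_M"),
  analysis = c("onset_s", "prominence_fraction", "bin_width_s", "n_bins",
               "event_time_s")
)

.check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad)) {
    stop("unknown config key(s) in ", where, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
}

#' Validate an experiment configuration
#'
#' Checks the block structure against the schema (unknown keys are
#' rejected), basic types and ranges, that exactly one drive source is
#' set, and that a referenced drive CSV exists. Returns the config
#' invisibly on success; stops with a descriptive error otherwise, before
#' any computation.
#'
#' @param cfg A config list (see [default_config()]).
#' @return `cfg`, invisibly.
#' @export
validate_config <- function(cfg) {
  if (!is.list(cfg)) stop("config must be a list", call. = FALSE)
  .check_keys(cfg, .CONFIG_SCHEMA$top, "top level")
  for (blk in c("geometry", "exchanger", "simulation", "drive",
                "analysis")) {
    if (is.null(cfg[[blk]])) {
      stop("missing config block: ", blk, call. = FALSE)
    }
    .check_keys(cfg[[blk]], .CONFIG_SCHEMA[[blk]], blk)
  }
  has_spec <- !is.null(cfg$drive$spec)
  has_csv <- !is.null(cfg$drive$csv)
  if (has_spec == has_csv) {
    stop("exactly one drive source required: drive$spec or drive$csv",
         call. = FALSE)
  }
  if (has_spec) {
    .check_keys(cfg$drive$spec, .CONFIG_SCHEMA$drive_spec, "drive$spec")
  } else {
    .check_keys(cfg$drive$csv, .CONFIG_SCHEMA$drive_csv, "drive$csv")
    if (is.null(cfg$drive$csv$path) || !file.exists(cfg$drive$csv$path)) {
      stop("drive CSV not found: ", cfg$drive$csv$path, call. = FALSE)
    }
    if (!is.null(cfg$drive$csv$rescale)) {
      .check_keys(cfg$drive$csv$rescale, .CONFIG_SCHEMA$drive_rescale,
                  "drive$csv$rescale")
    }
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  # construct the parameter objects: their validators do the range checks
  .config_objects(cfg)
  invisible(cfg)
}

# Build the typed parameter objects from a config (shared by
# validate_config and run_experiment).
.config_objects <- function(cfg) {
  geom <- mito_geometry(cfg$geometry$cyl_length_um, cfg$geometry$radius_um)
  ex <- exchanger_params(n_na = cfg$exchanger$n_na,
                         k_turnover = cfg$exchanger$k_turnover,
                         k_ca = cfg$exchanger$k_ca_M,
                         k_na = cfg$exchanger$k_na_M,
                         activation_enabled =
                           cfg$exchanger$activation_enabled,
                         k_act = cfg$exchanger$k_act_M,
                         h_act = cfg$exchanger$h_act)
  mem <- membrane_state(v_m = cfg$simulation$v_m_V,
                        temperature = cfg$simulation$temperature_K)
  sim <- simulation_params(n_ncx = cfg$simulation$n_ncx,
                           buffering_factor =
                             cfg$simulation$buffering_factor,
                           v_mito = cfg$simulation$v_mito_L,
                           geometry = geom,
                           rel_tol = cfg$simulation$rel_tol,
                           abs_tol = cfg$simulation$abs_tol,
                           max_step = cfg$simulation$max_step_s,
                           init_free = cfg$simulation$init_free_M,
                           null_tol = cfg$simulation$null_tol_ions_s,
                           seed = cfg$seed)
  list(geometry = geom, exchanger = ex, membrane = mem, simulation = sim)
}

#' Read a configuration from JSON or YAML
#'
#' Format chosen by file extension (`.json` vs `.yml`/`.yaml`). Missing
#' keys are filled from [default_config()]; the result is validated.
#'
#' @param path Config file path.
#' @return A validated config list.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yml = ,
    yaml = yaml::read_yaml(path),
    stop("config must be .json, .yml or .yaml", call. = FALSE))
  cfg <- default_config()
  cfg <- .merge_config(cfg, raw)
  # a file that names one drive source silences the default other one
  if (!is.null(raw$drive)) {
    if (!is.null(raw$drive$csv) && is.null(raw$drive$spec)) {
      cfg$drive$spec <- NULL
    }
    if (!is.null(raw$drive$spec) && is.null(raw$drive$csv)) {
      cfg$drive$csv <- NULL
    }
  }
  validate_config(cfg)
  cfg
}

# recursive merge: values in `over` win; unknown keys survive so that
# validate_config can reject them by name
.merge_config <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(base[[nm]]) &&
        nm %in% c("geometry", "exchanger", "simulation", "drive",
                  "analysis", "spec", "csv", "rescale")) {
      base[[nm]] <- .merge_config(base[[nm]], over[[nm]])
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}

# stable hash of a config for provenance records
.config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  unname(tools::md5sum(tmp))
}
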