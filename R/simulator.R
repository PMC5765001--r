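# Matrix free-Ca2+ dynamics: a well-mixed single compartment whose only
# Ca2+ transporter is a population of identical Na+-Ca2+ exchangers.

#' Mitochondrial geometry: capped cylinder
#'
#' @param cyl_length Cylinder length (um). Default 1.
#' @param radius Radius of cylinder and hemispherical caps (um). Default 0.5.
#' @return An object of class `mito_geometry`.
#' @examples
#' mito_volume(mito_geometry())   # 1.31e-15 l
#' @export
mito_geometry <- function(cyl_length = 1, radius = 0.5) {
  if (!is.numeric(cyl_length) || length(cyl_length) != 1L ||
      !is.finite(cyl_length) || cyl_length <= 0) {
    stop("`cyl_length` must be a single length > 0 (um)", call. = FALSE)
  }
  if (!is.numeric(radius) || length(radius) != 1L || !is.finite(radius) ||
      radius <= 0) {
    stop("`radius` must be a single length > 0 (um)", call. = FALSE)
  }
  structure(list(cyl_length = cyl_length, radius = radius),
            class = "mito_geometry")
}

#' Matrix volume of a capped-cylinder mitochondrion
#'
#' Volume of a cylinder of length `cyl_length` and radius `radius` with
#' hemispherical caps at both ends, converted from um^3 to litres
#' (1 um^3 = 1e-15 l). The default geometry gives 1.31e-15 l.
#'
#' @param geom A [mito_geometry()].
#' @return Volume in litres.
#' @export
mito_volume <- function(geom = mito_geometry()) {
  stopifnot(inherits(geom, "mito_geometry"))
  r <- geom$radius
  (pi * r^2 * geom$cyl_length + (4 / 3) * pi * r^3) * 1e-15
}

#' Simulation parameters for the matrix compartment
#'
#' @param n_ncx Number of exchangers in the inner membrane (integer in
#'   \[1, 1e6\]). Default 100.
#' @param buffering_factor Ratio of total to free matrix Ca2+ (>= 1);
#'   total = buffering_factor x free at all times. Default 100.
#' @param v_mito Matrix volume (l). Defaults to the capped-cylinder volume
#'   of `geometry`.
#' @param geometry A [mito_geometry()] used when `v_mito` is `NULL`.
#' @param rel_tol,abs_tol Solver tolerances; `abs_tol` is in molar free
#'   Ca2+. Defaults 1e-10 and 1e-14.
#' @param max_step Maximum solver step (s); `Inf` leaves stepping to the
#'   integrator.
#' @param init_free Optional free matrix Ca2+ initial condition (M)
#'   overriding steady-state initialisation, e.g. an ionomycin preload.
#' @param null_tol Dead band for per-sample mode labels (ions/s per
#'   exchanger): samples with `|flux| <= null_tol` are labelled `"null"`.
#'   Default 1 ion/s, i.e. less than one transport cycle per second.
#' @param seed Integer seed for any stochastic component.
#' @return An object of class `simulation_params`.
#' @export
simulation_params <- function(n_ncx = 100L, buffering_factor = 100,
                              v_mito = NULL, geometry = mito_geometry(),
                              rel_tol = 1e-10, abs_tol = 1e-14,
                              max_step = Inf, init_free = NULL,
                              null_tol = 1, seed = 1L) {
  if (!is.numeric(n_ncx) || length(n_ncx) != 1L || n_ncx != round(n_ncx) ||
      n_ncx < 1 || n_ncx > 1e6) {
    stop("`n_ncx` must be an integer in [1, 1e6]", call. = FALSE)
  }
  if (!is.numeric(buffering_factor) || length(buffering_factor) != 1L ||
      !is.finite(buffering_factor) || buffering_factor < 1) {
    stop("`buffering_factor` must be >= 1", call. = FALSE)
  }
  if (is.null(v_mito)) v_mito <- mito_volume(geometry)
  if (!is.numeric(v_mito) || length(v_mito) != 1L || !is.finite(v_mito) ||
      v_mito <= 0) {
    stop("`v_mito` must be a single volume > 0 (l)", call. = FALSE)
  }
  if (!is.null(init_free) &&
      (!is.numeric(init_free) || length(init_free) != 1L || init_free <= 0)) {
    stop("`init_free` must be a single concentration > 0 (M)", call. = FALSE)
  }
  stopifnot(rel_tol > 0, abs_tol > 0, max_step > 0, null_tol >= 0)
  structure(list(n_ncx = as.integer(n_ncx),
                 buffering_factor = buffering_factor, v_mito = v_mito,
                 rel_tol = rel_tol, abs_tol = abs_tol, max_step = max_step,
                 init_free = init_free, null_tol = null_tol,
                 seed = as.integer(seed)),
            class = "simulation_params")
}

#' Cytosolic Ca2+ drive trace
#'
#' The model's forcing input: a prescribed cytosolic free Ca2+ time series
#' (the empirical analogue is a calibrated fura-2 recording). There is no
#' feedback from the matrix onto the cytosol.
#'
#' @param times Sample times (s), strictly increasing, >= 2 samples.
#' @param ca_cyt Cytosolic free Ca2+ (M), same length, all > 0.
#' @param annotations Optional named list of event markers in seconds
#'   (e.g. `list(agonist_on = 60)`).
#' @return A data frame of class `drive_trace` with columns `time_s`,
#'   `ca_cyt_M`.
#' @export
drive_trace <- function(times, ca_cyt, annotations = NULL) {
  if (length(times) < 2L || length(ca_cyt) != length(times)) {
    stop("need >= 2 samples and equal-length `times` and `ca_cyt`",
         call. = FALSE)
  }
  if (any(!is.finite(times)) || any(diff(times) <= 0)) {
    stop("`times` must be finite and strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(ca_cyt)) || any(ca_cyt <= 0)) {
    stop("`ca_cyt` must be finite and > 0 (molar)", call. = FALSE)
  }
  structure(data.frame(time_s = as.numeric(times),
                       ca_cyt_M = as.numeric(ca_cyt)),
            annotations = annotations,
            class = c("drive_trace", "data.frame"))
}

#' Convert a whole-population ion flux to a free-concentration rate
#'
#' One mole-per-second bookkeeping step: an export flux of `total_flux`
#' ions/s from a matrix of volume `v_mito` lowers total matrix Ca2+ at
#' `total_flux / (v_mito N_A)` M/s, and free Ca2+ at 1/buffering_factor of
#' that.
#'
#' @param total_flux Whole-population flux (ions/s), positive = export.
#' @param params A [simulation_params()].
#' @return Rate of change of free matrix Ca2+ (M/s); negative when
#'   exporting.
#' @export
ions_to_concentration_rate <- function(total_flux, params) {
  stopifnot(inherits(params, "simulation_params"))
  -total_flux / (params$v_mito * .AVOGADRO * params$buffering_factor)
}

#' Steady-state initial condition for total matrix Ca2+
#'
#' The matrix is initialised at the exchanger's reversal point for the
#' drive's first sample, so the trajectory starts at zero net flux:
#' returns `buffering_factor x [Ca]_m^*` (total, M). If the activation gate
#' suppresses the flux so strongly at that point that it underflows to
#' zero, the configured `init_free` fallback is used with a warning.
#'
#' @param drive A [drive_trace()].
#' @param mem A [membrane_state()].
#' @param ex An [exchanger_params()].
#' @param params A [simulation_params()].
#' @param na_mito,na_cyt Fixed Na+ concentrations (M).
#' @return Initial total matrix Ca2+ (M).
#' @export
steady_state_init <- function(drive, mem, ex, params,
                              na_mito = 4.54e-3, na_cyt = 10e-3) {
  stopifnot(inherits(drive, "drive_trace"),
            inherits(params, "simulation_params"))
  ca_star <- equilibrium_matrix_ca(drive$ca_cyt_M[1L], na_mito, na_cyt,
                                   mem, ex)
  if (activation_factor(ca_star, ex) == 0) {
    if (is.null(params$init_free)) {
      warning("activation gate silences the exchanger at the reversal ",
              "point and no `init_free` fallback is configured; using the ",
              "reversal point anyway")
    } else {
      warning("activation gate silences the exchanger at the reversal ",
              "point; using the configured `init_free` fallback")
      return(params$buffering_factor * params$init_free)
    }
  }
  params$buffering_factor * ca_star
}

#' Simulate matrix free Ca2+ driven by a cytosolic trace
#'
#' Integrates the single-compartment balance
#' \deqn{d[Ca]_{m,total}/dt = - N_{NCX}\, f / (V_{mito} N_A),\qquad
#'       [Ca]_m = [Ca]_{m,total} / \mathrm{buffering\ factor},}
#' where `f` is the per-exchanger flux ([ncx_flux()], positive = export)
#' evaluated along the drive. Sodium concentrations are held fixed. The
#' drive is linearly interpolated between samples; output is returned on
#' the drive's time grid. Integration uses `deSolve::ode` (lsoda, stiff-
#' capable, adaptive).
#'
#' @param drive A [drive_trace()].
#' @param mem A [membrane_state()].
#' @param ex An [exchanger_params()].
#' @param params A [simulation_params()].
#' @param na_mito,na_cyt Fixed Na+ concentrations (M).
#' @return A data frame of class `matrix_trajectory` with columns `time_s`,
#'   `ca_total_M`, `ca_free_M`, `flux_ions_per_s` (per exchanger) and
#'   `mode` (`"forward"`, `"reverse"` or `"null"`); attributes record the
#'   parameters and solver diagnostics.
#' @examples
#' d <- generate_washout_drive(2e-7, 1e-8, switch_time = 30, duration = 60)
#' traj <- simulate_matrix(d, membrane_state(), exchanger_params(),
#'                         simulation_params())
#' head(traj)
#' @export
simulate_matrix <- function(drive, mem, ex, params,
                            na_mito = 4.54e-3, na_cyt = 10e-3) {
  stopifnot(inherits(drive, "drive_trace"), inherits(mem, "membrane_state"),
            inherits(ex, "exchanger_params"),
            inherits(params, "simulation_params"))
  drive_fun <- stats::approxfun(drive$time_s, drive$ca_cyt_M, rule = 2)
  scale <- params$n_ncx /
    (params$v_mito * .AVOGADRO * params$buffering_factor)

  x0 <- if (!is.null(params$init_free)) {
    params$init_free
  } else {
    steady_state_init(drive, mem, ex, params, na_mito, na_cyt) /
      params$buffering_factor
  }

  rhs <- function(t, y, p) {
    f <- .ncx_flux_core(y[1L], drive_fun(t), na_mito, na_cyt,
                        mem$v_m, mem$temperature, ex)
    list(-scale * f)
  }

  sol <- deSolve::ode(y = c(ca = x0), times = drive$time_s, func = rhs,
                      parms = NULL, method = "lsoda",
                      rtol = params$rel_tol, atol = params$abs_tol,
                      hmax = if (is.finite(params$max_step))
                        params$max_step else NULL)
  if (attr(sol, "istate")[1L] < 0) {
    bad <- max(sol[, "time"], na.rm = TRUE)
    stop("ODE solver failed near t = ", signif(bad, 6), " s", call. = FALSE)
  }
  free <- sol[, "ca"]
  if (any(!is.finite(free)) || any(free <= 0)) {
    t_bad <- drive$time_s[which(!is.finite(free) | free <= 0)[1L]]
    stop("non-positive matrix Ca2+ at t = ", signif(t_bad, 6),
         " s; check solver step configuration", call. = FALSE)
  }
  flux <- .ncx_flux_core(free, drive$ca_cyt_M, na_mito, na_cyt,
                         mem$v_m, mem$temperature, ex)
  mode <- rep("null", length(flux))
  mode[flux > params$null_tol] <- "forward"
  mode[flux < -params$null_tol] <- "reverse"

  structure(data.frame(time_s = drive$time_s,
                       ca_total_M = params$buffering_factor * free,
                       ca_free_M = free,
                       flux_ions_per_s = flux,
                       mode = mode,
                       stringsAsFactors = FALSE),
            membrane = mem, exchanger = ex, simulation = params,
            sodium = list(na_mito = na_mito, na_cyt = na_cyt),
            solver = list(steps = attr(sol, "istate")[3L],
                          rhs_evals = attr(sol, "istate")[4L]),
            class = c("matrix_trajectory", "data.frame"))
}

#' Fraction of simulated time spent in reverse mode
#'
#' Trapezoid-free occupancy: the fraction of the sampled duration whose
#' samples carry the `"reverse"` mode label (flux below the dead band in
#' the import direction). Sample i owns the interval up to sample i+1.
#'
#' @param traj A `matrix_trajectory`.
#' @return Fraction in \[0, 1\].
#' @export
reverse_mode_fraction <- function(traj) {
  stopifnot(inherits(traj, "matrix_trajectory"))
  dt <- diff(traj$time_s)
  sum(dt[traj$mode[-nrow(traj)] == "reverse"]) / sum(dt)
}

#' Sweep the exchanger count
#'
#' Runs [simulate_matrix()] for each exchanger count and summarises the
#' matrix free-Ca2+ oscillations of each run. More exchangers push the
#' matrix faster toward the per-phase reversal points, so the mean
#' oscillation amplitude grows with `n_ncx` and saturates at the gap
#' between the two closed-form equilibria.
#'
#' @param drive,mem,ex As for [simulate_matrix()].
#' @param base_params A [simulation_params()] whose `n_ncx` is replaced by
#'   each sweep value in turn.
#' @param n_values Integer vector of exchanger counts (each >= 1).
#' @param prominence_fraction Peak-detection threshold passed to
#'   [detect_peaks()].
#' @return Data frame with one row per count: `n_ncx`, `n_peaks`,
#'   `mean_amplitude` (M, free Ca2+), `reverse_fraction`, sorted by
#'   `n_ncx`.
#' @export
sweep_exchangers <- function(drive, mem, ex, base_params, n_values,
                             prominence_fraction = 0.2) {
  if (length(n_values) == 0L) {
    stop("`n_values` must be a nonempty vector of exchanger counts",
         call. = FALSE)
  }
  n_values <- sort(unique(as.integer(n_values)))
  rows <- lapply(n_values, function(n) {
    p <- base_params
    p$n_ncx <- n
    traj <- tryCatch(
      simulate_matrix(drive, mem, ex, p),
      error = function(e) stop("simulation failed at n_ncx = ", n, ": ",
                               conditionMessage(e), call. = FALSE))
    pk <- detect_peaks(traj$time_s, traj$ca_free_M, onset = 0,
                       prominence_fraction = prominence_fraction)
    data.frame(n_ncx = n,
               n_peaks = nrow(pk),
               mean_amplitude = if (nrow(pk)) mean(pk$amplitude) else 0,
               reverse_fraction = reverse_mode_fraction(traj))
  })
  do.call(rbind, rows)
}

#' Calibrate the exchanger turnover scale
#'
#' Finds the `k_turnover` at which `n_ncx` exchangers with the given
#' buffering carry matrix free Ca2+ across `target_fraction` of the gap
#' between the baseline and spike reversal points within every spike of a
#' square-wave drive (100 nM baseline, `peak` spikes of `spike_width`
#' seconds). This is the routine that fixed the package default for
#' [exchanger_params()].
#'
#' @param target_fraction Fraction of the reversal-point gap to traverse
#'   per spike. Default 0.9.
#' @param peak Spike concentration (M). Default 15 uM.
#' @param n_ncx,buffering_factor Population and buffering used for the
#'   calibration scenario. Defaults 100 and 100.
#' @param spike_width,period,n_spikes Square-wave layout (s, s, count).
#' @param mem A [membrane_state()].
#' @param interval Search interval for `k_turnover` (ions/s).
#' @return Calibrated `k_turnover` (ions/s).
#' @export
calibrate_turnover <- function(target_fraction = 0.9, peak = 1.5e-5,
                               n_ncx = 100L, buffering_factor = 100,
                               spike_width = 20, period = 60,
                               n_spikes = 10L, mem = membrane_state(),
                               interval = c(1, 1e6)) {
  spec <- oscillation_spec(baseline = 1e-7, peak = peak, period = period,
                           spike_width = spike_width, n_spikes = n_spikes,
                           duration = period * n_spikes, shape = "square",
                           desens_decay = 0, jitter_sd = 0, noise_sd = 0)
  drive <- generate_oscillating_drive(spec)
  ex0 <- exchanger_params()
  lo <- equilibrium_matrix_ca(1e-7, 4.54e-3, 10e-3, mem, ex0)
  hi <- equilibrium_matrix_ca(peak, 4.54e-3, 10e-3, mem, ex0)
  centres <- (seq_len(n_spikes) - 0.5) * period
  worst_fraction <- function(k) {
    ex <- exchanger_params(k_turnover = k)
    p <- simulation_params(n_ncx = n_ncx,
                           buffering_factor = buffering_factor)
    traj <- simulate_matrix(drive, mem, ex, p)
    fr <- vapply(centres, function(ct) {
      win <- traj$time_s >= ct - spike_width / 2 &
             traj$time_s <= ct + spike_width / 2
      (max(traj$ca_free_M[win]) - lo) / (hi - lo)
    }, numeric(1))
    min(fr)
  }
  stats::uniroot(function(k) worst_fraction(k) - target_fraction,
                 interval = interval, tol = 1e-3)$root
}
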