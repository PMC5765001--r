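# Synthetic cytosolic Ca2+ drives: agonist-evoked oscillation trains with
# receptor desensitisation, fura-2-style ratio rescaling, washout steps.

#' Specification of an agonist-evoked oscillation train
#'
#' Describes a leukotriene-type stimulus response: a baseline of ~100 nM
#' interrupted, after agonist application, by a regular train of Ca2+
#' spikes whose amplitude declines geometrically with spike number
#' (receptor desensitisation). Spikes are raised-cosine bumps by default;
#' `"gaussian"` and `"square"` shapes are available (square waves are used
#' for reversal-point calibration).
#'
#' @param baseline Resting cytosolic Ca2+ (M). Default 100 nM.
#' @param peak Concentration at the crest of the first spike (M). Default
#'   1.5 uM (measured bulk cytosolic rise); use 15 uM for the
#'   local/microdomain variant.
#' @param period Spike cadence (s). Default 50 s (about one spike per
#'   40-70 s).
#' @param spike_width Full width of one bump (s). Default 20 s.
#' @param n_spikes Number of spikes; defaults to `floor(duration/period)`.
#' @param duration Length of the post-onset window (s). Default 600 s.
#' @param desens_decay Fractional amplitude decline per spike in \[0, 1).
#'   Spike k has amplitude `(1 - desens_decay)^(k-1)` times the first.
#'   Default 0.05.
#' @param jitter_sd SD of Gaussian jitter on spike centres (s). Default 0.
#' @param noise_sd Optional Gaussian noise, expressed as a fraction of the
#'   baseline fluorescence ratio and added on the ratio scale (not the
#'   concentration scale). Default 0 (off).
#' @param seed Integer seed used for jitter and noise.
#' @param onset_time Agonist application time (s). Default 0.
#' @param dt Sample interval (s). Default 0.5 s (0.5 Hz acquisition).
#' @param shape `"cosine"`, `"gaussian"` or `"square"`.
#' @return An object of class `oscillation_spec`.
#' @examples
#' oscillation_spec(peak = 1.5e-5, n_spikes = 10)
#' @export
oscillation_spec <- function(baseline = 1e-7, peak = 1.5e-6, period = 50,
                             spike_width = 20, n_spikes = NULL,
                             duration = 600, desens_decay = 0.05,
                             jitter_sd = 0, noise_sd = 0, seed = 1L,
                             onset_time = 0, dt = 0.5,
                             shape = c("cosine", "gaussian", "square")) {
  shape <- match.arg(shape)
  if (!(peak > baseline && baseline > 0)) {
    stop("need `peak` > `baseline` > 0", call. = FALSE)
  }
  if (!(period > spike_width && spike_width > 0)) {
    stop("need `period` > `spike_width` > 0", call. = FALSE)
  }
  if (desens_decay < 0 || desens_decay >= 1) {
    stop("`desens_decay` must be in [0, 1)", call. = FALSE)
  }
  if (is.null(n_spikes)) {
    if (is.null(duration)) {
      stop("give `n_spikes` or `duration`", call. = FALSE)
    }
    n_spikes <- floor(duration / period)
  } else {
    n_spikes <- as.integer(n_spikes)
    if (n_spikes < 0) stop("`n_spikes` must be >= 0", call. = FALSE)
    if (is.null(duration)) duration <- n_spikes * period
    if (n_spikes > 0 && duration < n_spikes * period) {
      stop("`duration` too short for `n_spikes` spikes at this `period`",
           call. = FALSE)
    }
  }
  stopifnot(jitter_sd >= 0, noise_sd >= 0, dt > 0, onset_time >= 0,
            duration > 0)
  structure(list(baseline = baseline, peak = peak, period = period,
                 spike_width = spike_width, n_spikes = n_spikes,
                 duration = duration, desens_decay = desens_decay,
                 jitter_sd = jitter_sd, noise_sd = noise_sd,
                 seed = as.integer(seed), onset_time = onset_time,
                 dt = dt, shape = shape),
            class = "oscillation_spec")
}

# Default synthetic fura-2 ratio anchors (356/380 nm): resting and
# saturating ratio of the synthetic indicator.
.RATIO_MIN <- 0.3
.RATIO_MAX <- 2.5

#' Generate an oscillating cytosolic drive trace
#'
#' Deterministic given the spec's seed. Spike k (k = 1..n_spikes) is
#' centred at `onset_time + (k - 1/2) period` (plus jitter) with amplitude
#' `(peak - baseline)(1 - desens_decay)^(k-1)`. Optional noise is additive
#' Gaussian on the synthetic fluorescence ratio and is mapped back through
#' the logarithmic calibration, so it is multiplicative on concentration.
#'
#' @param spec An [oscillation_spec()].
#' @return A [drive_trace()] with annotation `agonist_on = onset_time`.
#' @examples
#' d <- generate_oscillating_drive(oscillation_spec(n_spikes = 3,
#'                                                  duration = 150))
#' range(d$ca_cyt_M)
#' @export
generate_oscillating_drive <- function(spec) {
  stopifnot(inherits(spec, "oscillation_spec"))
  times <- seq(0, spec$onset_time + spec$duration, by = spec$dt)
  conc <- rep(spec$baseline, length(times))
  if (spec$n_spikes > 0) {
    rng <- .with_seed(spec$seed, {
      stats::rnorm(spec$n_spikes, sd = spec$jitter_sd)
    })
    centres <- spec$onset_time + (seq_len(spec$n_spikes) - 0.5) *
      spec$period + rng
    amps <- (spec$peak - spec$baseline) *
      (1 - spec$desens_decay)^(seq_len(spec$n_spikes) - 1)
    w <- spec$spike_width
    for (k in seq_len(spec$n_spikes)) {
      u <- (times - centres[k]) / w
      bump <- switch(spec$shape,
        cosine   = ifelse(abs(u) <= 0.5, 0.5 * (1 + cos(2 * pi * u)), 0),
        gaussian = exp(-0.5 * (u / 0.25)^2),
        square   = as.numeric(abs(u) <= 0.5))
      conc <- conc + amps[k] * bump
    }
  }
  if (spec$noise_sd > 0) {
    r <- .conc_to_ratio(conc, low = spec$baseline, high = spec$peak)
    r <- r + .with_seed(spec$seed + 1L, {
      stats::rnorm(length(r), sd = spec$noise_sd * .RATIO_MIN)
    })
    conc <- .ratio_to_conc(r, low = spec$baseline, high = spec$peak)
  }
  drive_trace(times, conc,
              annotations = list(agonist_on = spec$onset_time))
}

# Evaluate expr with a local RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

# Fixed-anchor logarithmic calibration between concentration and the
# synthetic ratio scale [.RATIO_MIN, .RATIO_MAX].
.conc_to_ratio <- function(conc, low, high) {
  .RATIO_MIN + (.RATIO_MAX - .RATIO_MIN) *
    log(conc / low) / log(high / low)
}
.ratio_to_conc <- function(r, low, high) {
  low * (high / low)^((r - .RATIO_MIN) / (.RATIO_MAX - .RATIO_MIN))
}

#' Dimensionless fluorescence ratio trace
#'
#' @param times Sample times (s), strictly increasing.
#' @param ratio Fluorescence ratio (e.g. 356/380 nm), finite.
#' @return A data frame of class `ratio_trace` with columns `time_s`,
#'   `ratio`.
#' @export
ratio_trace <- function(times, ratio) {
  if (length(times) < 2L || length(ratio) != length(times)) {
    stop("need >= 2 samples and equal-length `times` and `ratio`",
         call. = FALSE)
  }
  if (any(!is.finite(times)) || any(diff(times) <= 0)) {
    stop("`times` must be finite and strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(ratio))) {
    stop("`ratio` must be finite", call. = FALSE)
  }
  structure(data.frame(time_s = as.numeric(times),
                       ratio = as.numeric(ratio)),
            class = c("ratio_trace", "data.frame"))
}

#' Rescale a fluorescence ratio trace logarithmically to concentration
#'
#' Log-linear calibration anchored at the trace's own extrema: the minimum
#' ratio maps to `low`, the maximum to `high`, and intermediate ratios
#' interpolate exponentially,
#' \deqn{C(r) = low \,(high/low)^{(r - r_{min})/(r_{max} - r_{min})}.}
#' By construction the result is invariant to any affine transformation of
#' the ratio.
#'
#' @param trace A [ratio_trace()].
#' @param low Concentration assigned to the minimum ratio (M). Default
#'   100 nM.
#' @param high Concentration assigned to the maximum ratio (M); 1.5 uM or
#'   15 uM in the standard scenarios.
#' @return A [drive_trace()].
#' @examples
#' rt <- ratio_trace(0:10, c(1, 1, 2, 1, 3, 1, 2, 1, 1, 1, 1))
#' scale_ratio_log(rt, high = 1.5e-5)
#' @export
scale_ratio_log <- function(trace, low = 1e-7, high) {
  stopifnot(inherits(trace, "ratio_trace"))
  if (!(high > low && low > 0)) stop("need `high` > `low` > 0",
                                     call. = FALSE)
  r_min <- min(trace$ratio)
  r_max <- max(trace$ratio)
  if (r_max <= r_min) {
    stop("flat ratio trace: cannot normalise", call. = FALSE)
  }
  conc <- low * (high / low)^((trace$ratio - r_min) / (r_max - r_min))
  # anchor the endpoints exactly (the power form can be off by 1 ulp)
  conc[trace$ratio == r_min] <- low
  conc[trace$ratio == r_max] <- high
  drive_trace(trace$time_s, conc)
}

#' Convert a drive trace to a synthetic fluorescence ratio
#'
#' Inverse of [scale_ratio_log()] against fixed synthetic-indicator
#' anchors; used for round-trip testing of the logarithmic calibration and
#' for building ratio-domain fixtures.
#'
#' @param drive A [drive_trace()].
#' @param low,high Concentrations mapped to the anchor ratios (M).
#' @return A [ratio_trace()].
#' @export
ratio_from_drive <- function(drive, low = 1e-7, high) {
  stopifnot(inherits(drive, "drive_trace"))
  if (!(high > low && low > 0)) stop("need `high` > `low` > 0",
                                     call. = FALSE)
  ratio_trace(drive$time_s,
              .conc_to_ratio(drive$ca_cyt_M, low = low, high = high))
}

#' Generate a washout (BAPTA-style) step drive
#'
#' Two-level trace for forward-mode decay experiments: cytosolic Ca2+ held
#' at `pre_level`, then stepped (optionally with a brief linear ramp) to
#' `post_level` at `switch_time`.
#'
#' @param pre_level,post_level Concentrations before/after the switch (M).
#' @param switch_time Washout time (s), strictly inside `(0, duration)`.
#' @param duration Total trace length (s).
#' @param ramp Ramp width (s); 0 gives a sharp step. Default 0.
#' @param dt Sample interval (s). Default 0.5.
#' @return A [drive_trace()] with annotation `washout = switch_time`.
#' @examples
#' generate_washout_drive(2e-7, 1e-8, switch_time = 300, duration = 600)
#' @export
generate_washout_drive <- function(pre_level, post_level, switch_time,
                                   duration, ramp = 0, dt = 0.5) {
  if (pre_level <= 0 || post_level <= 0) {
    stop("levels must be > 0", call. = FALSE)
  }
  if (!(switch_time > 0 && switch_time < duration)) {
    stop("need 0 < `switch_time` < `duration`", call. = FALSE)
  }
  stopifnot(ramp >= 0, dt > 0)
  times <- seq(0, duration, by = dt)
  if (ramp > 0) {
    frac <- pmin(pmax((times - switch_time) / ramp, 0), 1)
  } else {
    frac <- as.numeric(times >= switch_time)
  }
  conc <- pre_level * (1 - frac) + post_level * frac
  drive_trace(times, conc, annotations = list(washout = switch_time))
}
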