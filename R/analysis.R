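# Oscillation metrics: peak detection with local-baseline prominence,
# 200-s bin counts, amplitude by oscillation number, washout decay
# half-times, forward/reverse mode segmentation.

#' Detect oscillation peaks in a time series
#'
#' Local maxima after `onset` (plateau tops count once, at their centre),
#' accepted when their amplitude above the local baseline reaches
#' `prominence_fraction` of the trace's post-onset excursion
#' (global max - global min). The local baseline of a peak is the minimum
#' of the trace between the previous accepted peak (or the onset) and the
#' peak, which makes amplitudes robust to slow drift. Deterministic; a
#' flat trace yields an empty peak set.
#'
#' @param times Sample times (s), strictly increasing.
#' @param values Trace values (any units).
#' @param onset Ignore samples before this time (s). Default 0.
#' @param prominence_fraction Acceptance threshold as a fraction of the
#'   post-onset excursion, in (0, 1). Default 0.2.
#' @return A data frame of class `peak_set` with columns `time`, `value`,
#'   `baseline`, `amplitude`; attribute `prominence_threshold` records the
#'   absolute threshold used.
#' @examples
#' d <- generate_oscillating_drive(oscillation_spec(n_spikes = 5,
#'                                                  duration = 250))
#' detect_peaks(d$time_s, d$ca_cyt_M)
#' @export
detect_peaks <- function(times, values, onset = 0,
                         prominence_fraction = 0.2) {
  stopifnot(length(times) == length(values), length(times) >= 2,
            all(diff(times) > 0),
            prominence_fraction > 0, prominence_fraction < 1)
  keep <- times >= onset
  t <- as.numeric(times[keep])
  v <- as.numeric(values[keep])
  empty <- structure(
    data.frame(time = numeric(0), value = numeric(0),
               baseline = numeric(0), amplitude = numeric(0)),
    prominence_threshold = NA_real_, class = c("peak_set", "data.frame"))
  if (length(v) < 3L) return(empty)
  excursion <- max(v) - min(v)
  if (excursion == 0) return(empty)
  threshold <- prominence_fraction * excursion

  # Candidate maxima, plateau-aware: a peak is a (possibly length-1) run
  # of equal values whose last nonzero slope before is + and after is -.
  d <- diff(v)
  s <- sign(d)
  nz <- which(s != 0)
  cand <- integer(0)
  if (length(nz) >= 2) {
    for (j in seq_len(length(nz) - 1L)) {
      if (s[nz[j]] == 1 && s[nz[j + 1L]] == -1) {
        # plateau spans indices (nz[j]+1) .. nz[j+1]
        cand <- c(cand, floor((nz[j] + 1L + nz[j + 1L]) / 2))
      }
    }
  }
  if (length(cand) == 0L) return(empty)

  rows <- list()
  prev_idx <- 1L
  for (i in cand) {
    base <- min(v[prev_idx:i])
    amp <- v[i] - base
    if (amp >= threshold) {
      rows[[length(rows) + 1L]] <-
        data.frame(time = t[i], value = v[i], baseline = base,
                   amplitude = amp)
      prev_idx <- i
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  structure(out, prominence_threshold = threshold,
            class = c("peak_set", "data.frame"))
}

#' Count oscillations per time bin
#'
#' Half-open binning from the stimulus onset: bin k (k = 0..n_bins-1)
#' covers `[onset + k w, onset + (k+1) w)`, so a peak exactly on a
#' boundary belongs to the later bin. Peaks beyond the last bin (or before
#' onset) are not counted; their number is reported in the `ignored`
#' attribute.
#'
#' @param peaks A `peak_set` from [detect_peaks()].
#' @param onset Stimulus application time (s). Default 0.
#' @param bin_width Bin width (s). Default 200.
#' @param n_bins Number of bins. Default 3.
#' @return Integer vector of length `n_bins`; attribute `ignored` gives
#'   the number of out-of-window peaks.
#' @examples
#' pk <- data.frame(time = seq(25, 575, by = 50))
#' count_per_bin(structure(pk, class = c("peak_set", "data.frame")))
#' @export
count_per_bin <- function(peaks, onset = 0, bin_width = 200, n_bins = 3L) {
  stopifnot(inherits(peaks, "peak_set"), bin_width > 0, n_bins >= 1)
  idx <- floor((peaks$time - onset) / bin_width)
  inside <- idx >= 0 & idx < n_bins
  counts <- tabulate(idx[inside] + 1L, nbins = n_bins)
  structure(as.integer(counts), ignored = sum(!inside))
}

#' Oscillation amplitude by oscillation number
#'
#' The k-th entry is the amplitude (value minus local baseline) of the
#' k-th peak in time order, i.e. the amplitude-versus-peak-number series
#' used to quantify receptor desensitisation.
#'
#' @param peaks A `peak_set`.
#' @return Numeric vector of amplitudes (possibly empty).
#' @export
amplitude_by_number <- function(peaks) {
  stopifnot(inherits(peaks, "peak_set"))
  peaks$amplitude
}

#' Decay half-time after a washout event
#'
#' Time taken, from `event_time`, for the trace to first fall to halfway
#' between its value at the event and `baseline`, using linear
#' interpolation between samples. If the trace never reaches the
#' half-level the result is `NA` with attribute `undefined = TRUE` (a
#' flagged outcome, not an error): a trace that stays up is the signature
#' of a transporter that cannot run forward under those conditions.
#'
#' @param times,values The trace.
#' @param event_time Washout event time (s).
#' @param baseline Level the trace decays toward (trace units).
#' @return Half-time in seconds, or flagged `NA`.
#' @examples
#' t <- seq(0, 120, by = 0.5)
#' decay_half_time(t, exp(-t / 26.83), event_time = 0, baseline = 0)
#' @export
decay_half_time <- function(times, values, event_time, baseline) {
  stopifnot(length(times) == length(values), all(diff(times) > 0))
  if (event_time < times[1L] || event_time > times[length(times)]) {
    stop("`event_time` outside the trace", call. = FALSE)
  }
  v0 <- stats::approx(times, values, xout = event_time)$y
  if (v0 <= baseline) {
    stop("trace does not exceed `baseline` at `event_time`", call. = FALSE)
  }
  half <- baseline + (v0 - baseline) / 2
  after <- times >= event_time
  t <- c(event_time, times[after & times > event_time])
  v <- c(v0, values[after & times > event_time])
  below <- which(v <= half)
  if (length(below) == 0L) {
    return(structure(NA_real_, undefined = TRUE))
  }
  i <- below[1L]
  if (i == 1L) return(0)
  # linear interpolation across the crossing
  t_cross <- t[i - 1L] + (half - v[i - 1L]) * (t[i] - t[i - 1L]) /
    (v[i] - v[i - 1L])
  t_cross - event_time
}

#' Segment a simulated trajectory into forward/reverse mode intervals
#'
#' Maximal runs of constant flux sign: reverse where the per-exchanger
#' flux is below `-null_tol` (Ca2+ import), forward where above
#' `+null_tol`. Sub-threshold ("null") samples attach to the following
#' signed segment; trailing nulls attach to the preceding one.
#'
#' @param traj A `matrix_trajectory` from [simulate_matrix()], or any data
#'   frame with columns `time_s` and `flux_ions_per_s`.
#' @param null_tol Dead band (ions/s); defaults to the trajectory's own
#'   simulation setting, else 0.
#' @return Data frame with columns `start`, `end` (s) and `mode`
#'   (`"forward"`/`"reverse"`).
#' @export
classify_modes <- function(traj, null_tol = NULL) {
  stopifnot(is.data.frame(traj),
            all(c("time_s", "flux_ions_per_s") %in% names(traj)))
  if (is.null(null_tol)) {
    sim <- attr(traj, "simulation")
    null_tol <- if (!is.null(sim)) sim$null_tol else 0
  }
  s <- integer(nrow(traj))
  s[traj$flux_ions_per_s > null_tol] <- 1L
  s[traj$flux_ions_per_s < -null_tol] <- -1L
  # attach zero/null samples to the following signed sample
  filled <- s
  last <- 0L
  for (i in rev(seq_along(s))) {
    if (filled[i] == 0L) filled[i] <- last else last <- filled[i]
  }
  # trailing nulls (still 0): attach to preceding signed sample
  last <- 0L
  for (i in seq_along(filled)) {
    if (filled[i] == 0L) filled[i] <- last else last <- filled[i]
  }
  keep <- filled != 0L
  if (!any(keep)) {
    return(data.frame(start = numeric(0), end = numeric(0),
                      mode = character(0)))
  }
  r <- rle(filled[keep])
  idx <- which(keep)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  data.frame(start = traj$time_s[idx[starts]],
             end = traj$time_s[idx[ends]],
             mode = ifelse(r$values > 0, "forward", "reverse"),
             stringsAsFactors = FALSE)
}

#' Summarise an oscillatory trace the standard way
#'
#' One call producing the full quantification bundle: detected peaks,
#' oscillations per 200-s bin from onset, amplitude by oscillation number,
#' an optional washout decay half-time, and (when a simulated trajectory
#' is supplied) forward/reverse mode segments.
#'
#' @param times,values The trace to quantify (e.g. matrix free Ca2+ or a
#'   cytosolic drive).
#' @param onset Stimulus onset (s). Default 0.
#' @param prominence_fraction Passed to [detect_peaks()].
#' @param bin_width,n_bins Passed to [count_per_bin()].
#' @param event_time,event_baseline Optional washout event for
#'   [decay_half_time()]; baseline defaults to the trace minimum after the
#'   event.
#' @param trajectory Optional `matrix_trajectory` for mode segmentation.
#' @return An object of class `oscillation_summary`: a list with elements
#'   `peaks`, `bin_counts`, `amplitude_series`, `decay_half_time`,
#'   `mode_segments` and `parameters`.
#' @export
summarize_oscillations <- function(times, values, onset = 0,
                                   prominence_fraction = 0.2,
                                   bin_width = 200, n_bins = 3L,
                                   event_time = NULL,
                                   event_baseline = NULL,
                                   trajectory = NULL) {
  peaks <- detect_peaks(times, values, onset = onset,
                        prominence_fraction = prominence_fraction)
  bins <- count_per_bin(peaks, onset = onset, bin_width = bin_width,
                        n_bins = n_bins)
  dht <- NULL
  if (!is.null(event_time)) {
    if (is.null(event_baseline)) {
      event_baseline <- min(values[times >= event_time])
    }
    dht <- decay_half_time(times, values, event_time, event_baseline)
  }
  segs <- if (!is.null(trajectory)) classify_modes(trajectory) else NULL
  structure(list(peaks = peaks,
                 bin_counts = bins,
                 amplitude_series = amplitude_by_number(peaks),
                 decay_half_time = dht,
                 mode_segments = segs,
                 parameters = list(onset = onset,
                                   prominence_fraction = prominence_fraction,
                                   prominence_threshold =
                                     attr(peaks, "prominence_threshold"),
                                   bin_width = bin_width, n_bins = n_bins)),
            class = "oscillation_summary")
}

#' @export
print.oscillation_summary <- function(x, ...) {
  cat("Oscillation summary\n")
  cat(sprintf("  peaks          : %d\n", nrow(x$peaks)))
  cat(sprintf("  bin counts     : %s (ignored: %d)\n",
              paste(x$bin_counts, collapse = ", "),
              attr(x$bin_counts, "ignored")))
  if (length(x$amplitude_series)) {
    cat(sprintf("  mean amplitude : %g\n", mean(x$amplitude_series)))
  }
  if (!is.null(x$decay_half_time)) {
    cat(sprintf("  decay half-time: %s s\n",
                if (is.na(x$decay_half_time)) "undefined"
                else signif(x$decay_half_time, 3)))
  }
  if (!is.null(x$mode_segments)) {
    cat(sprintf("  mode segments  : %d (%d reverse)\n",
                nrow(x$mode_segments),
                sum(x$mode_segments$mode == "reverse")))
  }
  invisible(x)
}
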