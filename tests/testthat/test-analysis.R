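# Oscillation metrics: peak detection, binning, amplitudes, half-times,
# mode segmentation.

test_that("flat and near-flat traces yield no peaks", {
  t <- seq(0, 100, by = 0.5)
  expect_identical(nrow(detect_peaks(t, rep(1, length(t)))), 0L)
  # excursions below the prominence threshold are ignored
  v <- 1 + 0.01 * sin(t)
  v[t > 50 & t < 60] <- v[t > 50 & t < 60] + 1
  expect_identical(nrow(detect_peaks(t, v, prominence_fraction = 0.2)), 1L)
})

test_that("a constructed bump train is recovered exactly", {
  d <- generate_oscillating_drive(oscillation_spec(
    n_spikes = 10L, duration = 600, period = 60))
  pk <- detect_peaks(d$time_s, d$ca_cyt_M)
  expect_identical(nrow(pk), 10L)
  expect_true(all(abs(pk$time - (1:10 - 0.5) * 60) <= 0.5))
  # independent cross-check with a generic peak finder
  skip_if_not_installed("pracma")
  ref <- pracma::findpeaks(d$ca_cyt_M,
                           minpeakheight = 1e-7 + 0.2 *
                             diff(range(d$ca_cyt_M)))
  expect_identical(nrow(ref), 10L)
})

test_that("a single triangular bump has amplitude equal to its height", {
  t <- 0:20
  v <- pmax(0, 5 - abs(t - 10))
  pk <- detect_peaks(t, v)
  expect_identical(nrow(pk), 1L)
  expect_identical(pk$amplitude, 5)
  expect_identical(pk$time, 10)
})

test_that("plateau-topped peaks are counted once", {
  t <- 0:12
  v <- c(0, 0, 1, 2, 2, 2, 1, 0, 1, 3, 1, 0, 0)
  pk <- detect_peaks(t, v)
  expect_identical(nrow(pk), 2L)
  expect_identical(pk$time[1], 4)  # centre of the plateau
})

test_that("binning is half-open from onset and conserves peak counts", {
  pk <- structure(data.frame(time = seq(25, 575, by = 50)),
                  class = c("peak_set", "data.frame"))
  expect_identical(as.integer(count_per_bin(pk)), c(4L, 4L, 4L))

  empty <- structure(data.frame(time = numeric(0)),
                     class = c("peak_set", "data.frame"))
  expect_identical(as.integer(count_per_bin(empty)), c(0L, 0L, 0L))

  # boundary peak joins the later bin
  bd <- structure(data.frame(time = c(199.9, 200)),
                  class = c("peak_set", "data.frame"))
  expect_identical(as.integer(count_per_bin(bd)), c(1L, 1L, 0L))

  # peaks beyond the window are reported, not silently dropped
  far <- structure(data.frame(time = c(100, 700)),
                   class = c("peak_set", "data.frame"))
  counts <- count_per_bin(far)
  expect_identical(sum(counts) + attr(counts, "ignored"), 2L)
})

test_that("amplitude-by-number reflects construction order", {
  d <- generate_oscillating_drive(oscillation_spec(
    desens_decay = 0.05, n_spikes = 8L, duration = 400))
  amps <- amplitude_by_number(detect_peaks(d$time_s, d$ca_cyt_M))
  expect_identical(length(amps), 8L)
  expect_true(all(diff(amps) < 0))

  flatish <- generate_oscillating_drive(oscillation_spec(
    desens_decay = 0, n_spikes = 5L, duration = 250))
  a <- amplitude_by_number(detect_peaks(flatish$time_s,
                                        flatish$ca_cyt_M))
  expect_equal(max(a) / min(a), 1, tolerance = 1e-6)

  empty <- detect_peaks(0:10, rep(0, 11))
  expect_identical(amplitude_by_number(empty), numeric(0))
})

test_that("decay half-time matches closed forms", {
  t <- seq(0, 200, by = 0.1)
  # exponential: half-time = tau * ln 2 = 26.83 * 0.6931 = 18.60 s
  expect_equal(signif(decay_half_time(t, 2 + exp(-t / 26.83),
                                      event_time = 0, baseline = 2), 3),
               18.6)
  # linear decay from A to baseline over T: half-time T/2
  T <- 80
  v_lin <- pmax(1 - t / T, 0)
  expect_equal(decay_half_time(t, v_lin, event_time = 0, baseline = 0),
               T / 2, tolerance = 1e-10)
  # measured from the event marker, not from the trace start
  expect_equal(signif(decay_half_time(t, 2 + exp(-pmax(t - 50, 0) / 26.83),
                                      event_time = 50, baseline = 2), 3),
               18.6)
})

test_that("a non-decaying trace gives a flagged undefined half-time", {
  t <- 0:100
  out <- decay_half_time(t, rep(5, 101), event_time = 10, baseline = 0)
  expect_true(is.na(out))
  expect_true(attr(out, "undefined"))
  expect_error(decay_half_time(t, rep(5, 101), event_time = 10,
                               baseline = 6), "exceed")
})

test_that("mode segmentation run-length encodes the flux sign", {
  mk <- function(flux) data.frame(time_s = seq_along(flux) - 1,
                                  flux_ions_per_s = flux)
  all_pos <- classify_modes(mk(rep(2, 5)))
  expect_identical(nrow(all_pos), 1L)
  expect_identical(all_pos$mode, "forward")
  expect_identical(all_pos$start, 0)
  expect_identical(all_pos$end, 4)

  three <- classify_modes(mk(c(2, 2, -2, -2, 2)))
  expect_identical(three$mode, c("forward", "reverse", "forward"))

  # zero-flux samples attach to the following segment
  with_zero <- classify_modes(mk(c(2, 0, -2, -2, 2)))
  expect_identical(with_zero$mode, c("forward", "reverse", "forward"))
  expect_identical(with_zero$start[2], 1)
})

test_that("full-analysis summary recovers generator parameters", {
  d <- generate_oscillating_drive(oscillation_spec(
    desens_decay = 0.05, period = 50, duration = 600))
  s <- summarize_oscillations(d$time_s, d$ca_cyt_M)
  expect_identical(nrow(s$peaks), 12L)
  expect_identical(as.integer(s$bin_counts), c(4L, 4L, 4L))
  expect_identical(sum(s$bin_counts) + attr(s$bin_counts, "ignored"),
                   nrow(s$peaks))
  ratios <- s$amplitude_series[-1] / s$amplitude_series[-12]
  expect_equal(mean(ratios), 0.95, tolerance = 1e-3)
})

test_that("matrix peak count mirrors the drive peak count", {
  drive <- square_drive_15uM()
  traj <- simulate_matrix(drive, std_mem(), std_ex(),
                          simulation_params())
  n_drive <- nrow(detect_peaks(drive$time_s, drive$ca_cyt_M))
  n_matrix <- nrow(detect_peaks(traj$time_s, traj$ca_free_M))
  expect_identical(n_matrix, n_drive)
})
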