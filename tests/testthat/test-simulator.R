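# Matrix compartment: geometry, unit bookkeeping, steady-state
# initialisation, ODE trajectories, exchanger-count sweeps.

test_that("capped-cylinder volume matches the stated geometry", {
  expect_equal(signif(mito_volume(mito_geometry(1, 0.5)), 3), 1.31e-15)
  # hand evaluation: pi*0.25*2 + (4/3)*pi*0.125 = 2.0944 um^3
  expect_equal(mito_volume(mito_geometry(2, 0.5)), 2.0944e-15,
               tolerance = 1e-4)
  # degenerate solid: volume -> 0 with the radius
  expect_lt(mito_volume(mito_geometry(1, 1e-6)), 1e-26)
  expect_error(mito_geometry(0, 0.5), "> 0")
  expect_error(mito_geometry(1, -1), "> 0")
})

test_that("population flux converts to a free-concentration rate", {
  p100 <- simulation_params(buffering_factor = 100, v_mito = 1.31e-15)
  # 1e5 / (1.31e-15 * 6.022e23 * 100) = 1.2676e-6 M/s, falling
  expect_equal(ions_to_concentration_rate(1e5, p100), -1.2676e-6,
               tolerance = 1e-4)
  expect_identical(ions_to_concentration_rate(0, p100), 0)
  p1000 <- simulation_params(buffering_factor = 1000, v_mito = 1.31e-15)
  expect_equal(ions_to_concentration_rate(1e5, p1000),
               ions_to_concentration_rate(1e5, p100) / 10)
})

test_that("steady-state initialisation is a fixed point of the dynamics", {
  mem <- std_mem()
  ex <- std_ex()
  sim <- simulation_params()
  flat <- generate_oscillating_drive(
    oscillation_spec(n_spikes = 0L, duration = 600))
  init_total <- steady_state_init(flat, mem, ex, sim)
  expect_equal(init_total / sim$buffering_factor, 4.2946e-9,
               tolerance = 1e-3)
  traj <- simulate_matrix(flat, mem, ex, sim)
  drift <- abs(traj$ca_free_M - traj$ca_free_M[1]) / traj$ca_free_M[1]
  expect_lt(max(drift), 1e-3)

  # +50% perturbation relaxes monotonically back to the reversal point
  sim_p <- simulation_params(init_free = 1.5 * init_total /
                               sim$buffering_factor)
  traj_p <- simulate_matrix(flat, mem, ex, sim_p)
  expect_true(all(diff(traj_p$ca_free_M) <= 1e-18))
  expect_equal(traj_p$ca_free_M[nrow(traj_p)],
               init_total / sim$buffering_factor, tolerance = 1e-3)
})

test_that("total and free matrix Ca2+ keep the exact buffering ratio", {
  traj <- simulate_matrix(square_drive_15uM(), std_mem(), std_ex(),
                          simulation_params())
  expect_identical(traj$ca_total_M, 100 * traj$ca_free_M)
  expect_true(all(traj$ca_free_M > 0))
})

test_that("a 10-spike square drive yields 10 matrix peaks with mode switching", {
  drive <- square_drive_15uM()
  traj <- simulate_matrix(drive, std_mem(), std_ex(), simulation_params())
  pk <- detect_peaks(traj$time_s, traj$ca_free_M)
  expect_identical(nrow(pk), 10L)

  centres <- (1:10 - 0.5) * 60
  for (ct in centres) {
    spike <- traj$time_s > ct - 9.5 & traj$time_s < ct + 9.5
    expect_true(all(traj$flux_ions_per_s[spike] < 0))
    inter <- traj$time_s > ct + 10.5 & traj$time_s < ct + 49.5
    if (any(inter)) {
      expect_true(all(traj$flux_ions_per_s[inter] > -1))
      expect_gt(max(traj$flux_ions_per_s[inter]), 0)
    }
  }
  segs <- classify_modes(traj)
  expect_gte(sum(segs$mode == "reverse"), 10)
  # segments alternate by construction of the run-length encoding
  expect_true(all(segs$mode[-1] != segs$mode[-nrow(segs)]))
})

test_that("smaller cytosolic spikes give smaller matrix excursions", {
  mk <- function(peak) generate_oscillating_drive(oscillation_spec(
    baseline = 1e-7, peak = peak, period = 60, spike_width = 20,
    n_spikes = 10L, duration = 600, desens_decay = 0, shape = "square"))
  t15 <- simulate_matrix(mk(1.5e-5), std_mem(), std_ex(),
                         simulation_params())
  t1.5 <- simulate_matrix(mk(1.5e-6), std_mem(), std_ex(),
                          simulation_params())
  a15 <- detect_peaks(t15$time_s, t15$ca_free_M)$amplitude
  a1.5 <- detect_peaks(t1.5$time_s, t1.5$ca_free_M)$amplitude
  expect_identical(length(a15), length(a1.5))
  expect_true(all(a1.5 < a15))
})

test_that("stronger buffering damps the free-Ca2+ oscillation", {
  drive <- square_drive_15uM()
  amp <- function(b) {
    traj <- simulate_matrix(drive, std_mem(), std_ex(),
                            simulation_params(buffering_factor = b))
    mean(detect_peaks(traj$time_s, traj$ca_free_M)$amplitude)
  }
  expect_lt(amp(1000), amp(100))
})

test_that("trajectories are insensitive to solver tolerances and grid", {
  drive <- square_drive_15uM()
  mem <- std_mem(); ex <- std_ex()
  t_ref <- simulate_matrix(drive, mem, ex, simulation_params())
  t_tight <- simulate_matrix(drive, mem, ex,
                             simulation_params(rel_tol = 5e-9,
                                               abs_tol = 5e-13))
  expect_lt(max(abs(t_tight$ca_free_M - t_ref$ca_free_M) /
                  t_ref$ca_free_M), 1e-3)
  # doubled time grid, compared on the common samples
  fine <- drive_trace(seq(0, 600, by = 0.25),
                      approx(drive$time_s, drive$ca_cyt_M,
                             xout = seq(0, 600, by = 0.25))$y)
  t_fine <- simulate_matrix(fine, mem, ex, simulation_params())
  common <- t_fine$time_s %in% t_ref$time_s
  expect_lt(max(abs(t_fine$ca_free_M[common] - t_ref$ca_free_M) /
                  t_ref$ca_free_M), 1e-3)
})

test_that("amplitude grows with exchanger count toward the reversal gap", {
  drive <- square_drive_15uM()
  sw <- sweep_exchangers(drive, std_mem(), std_ex(), simulation_params(),
                         n_values = c(1, 10, 100, 1000))
  expect_identical(sw$n_ncx, c(1L, 10L, 100L, 1000L))
  expect_true(all(diff(sw$mean_amplitude) >= 0))
  gap <- std_equilibrium(1.5e-5) - std_equilibrium(1e-7)
  expect_true(all(sw$mean_amplitude <= gap * 1.001))
  # enough transporters equilibrate within each phase: amplitude ~ gap
  expect_gt(sw$mean_amplitude[4], 0.99 * gap)
  # single row consistency with a direct run
  one <- sweep_exchangers(drive, std_mem(), std_ex(),
                          simulation_params(), n_values = 100)
  expect_equal(one$mean_amplitude, sw$mean_amplitude[3])
})

test_that("invalid sweeps and drives are rejected", {
  expect_error(sweep_exchangers(square_drive_15uM(), std_mem(), std_ex(),
                                simulation_params(), integer(0)),
               "nonempty")
  expect_error(drive_trace(c(0, 0, 1), c(1e-7, 1e-7, 1e-7)),
               "strictly increasing")
  expect_error(drive_trace(c(0, 1), c(1e-7, -1e-7)), "> 0")
  expect_error(simulation_params(n_ncx = 0), "n_ncx")
  expect_error(simulation_params(buffering_factor = 0.5), ">= 1")
})
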