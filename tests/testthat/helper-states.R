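# Shared fixtures: the standard depolarised-mitochondrion conditions and
# a deterministic random-state generator for property tests.

std_mem <- function() membrane_state(v_m = -0.02, temperature = 298)
std_ex <- function(...) exchanger_params(...)

# Closed-form reversal point under the standard Na+ gradient.
std_equilibrium <- function(ca_cyt, mem = std_mem(), ex = std_ex()) {
  equilibrium_matrix_ca(ca_cyt, 4.54e-3, 10e-3, mem, ex)
}

# Draw n random admissible (ions, mem, params) triples, log-uniform over
# physiological-ish ranges. Deterministic given seed.
random_states <- function(n, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    list(
      ions = ion_state(
        ca_mito = 10^stats::runif(1, -9, -4),
        ca_cyt = 10^stats::runif(1, -9, -4),
        na_mito = 10^stats::runif(1, -3, -1),
        na_cyt = 10^stats::runif(1, -3, -1)),
      mem = membrane_state(v_m = stats::runif(1, -0.2, 0.05),
                           temperature = stats::runif(1, 290, 310)),
      params = exchanger_params(
        n_na = sample(3:4, 1),
        k_turnover = 10^stats::runif(1, 1, 4),
        k_ca = 10^stats::runif(1, -6, -4),
        k_na = 10^stats::runif(1, -3, -1)))
  })
}

# 10-spike square-wave drive used for the mode-switching scenario.
square_drive_15uM <- function() {
  generate_oscillating_drive(oscillation_spec(
    baseline = 1e-7, peak = 1.5e-5, period = 60, spike_width = 20,
    n_spikes = 10L, duration = 600, desens_decay = 0, jitter_sd = 0,
    noise_sd = 0, shape = "square"))
}
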