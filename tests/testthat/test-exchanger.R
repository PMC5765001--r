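# Single-exchanger flux law: thermodynamic consistency, reversal point,
# activation gate, monotonicities, boundedness.

test_that("symmetric states carry no free energy and no flux", {
  ions <- ion_state(ca_mito = 1e-7, ca_cyt = 1e-7,
                    na_mito = 10e-3, na_cyt = 10e-3)
  mem <- membrane_state(v_m = 0)
  ex <- std_ex()
  expect_identical(cycle_free_energy(ions, mem, ex), 0)
  expect_identical(ncx_flux(ions, mem, ex), 0)
})

test_that("type validators reject inadmissible states", {
  expect_error(ion_state(0, 1e-7), "> 0")
  expect_error(ion_state(1e-7, -1e-7), "> 0")
  expect_error(membrane_state(v_m = 0.6), "0.5")
  expect_error(membrane_state(temperature = 0), "> 0")
  expect_error(exchanger_params(n_na = 2), "electrogenic")
  expect_error(exchanger_params(k_ca = 0), "> 0")
  expect_error(exchanger_params(h_act = 0.5), ">= 1")
})

test_that("reversal point matches the closed form and a bisection root", {
  mem <- std_mem()
  ex <- std_ex()
  # frozen values from the closed form (F = 96485 C/mol, R = 8.314):
  # 1e-7 * (4.54/10)^3 * exp(-0.77887) = 4.2946e-9 M
  eq_rest <- equilibrium_matrix_ca(1e-7, 4.54e-3, 10e-3, mem, ex)
  expect_equal(eq_rest, 4.2946e-9, tolerance = 1e-3)
  eq_spike <- equilibrium_matrix_ca(1.5e-5, 4.54e-3, 10e-3, mem, ex)
  expect_equal(eq_spike, 6.4419e-7, tolerance = 1e-3)

  # independent oracle: bracketing bisection on the flux itself
  for (ca_cyt in c(1e-7, 1.5e-5)) {
    root <- uniroot(function(x) {
      ncx_flux(ion_state(x, ca_cyt), mem, ex)
    }, interval = c(1e-12, 1e-4), tol = 1e-15)$root
    expect_equal(equilibrium_matrix_ca(ca_cyt, 4.54e-3, 10e-3, mem, ex),
                 root, tolerance = 1e-6)
  }

  # no driving asymmetry: equilibrium equals the cytosolic level
  expect_equal(equilibrium_matrix_ca(
    2e-7, 10e-3, 10e-3, membrane_state(v_m = 0), ex), 2e-7)
})

test_that("flux vanishes at the reversal point and free energy agrees", {
  mem <- std_mem()
  ex <- std_ex()
  for (ca_cyt in c(1e-7, 1.5e-6, 1.5e-5)) {
    eq <- std_equilibrium(ca_cyt, mem, ex)
    ions <- ion_state(eq, ca_cyt)
    expect_lt(abs(ncx_flux(ions, mem, ex)), 1e-12 * ex$k_turnover)
    expect_lt(abs(cycle_free_energy(ions, mem, ex)), 1e-9 * 8.314 * 298)
  }
})

test_that("energised resting mitochondria favour forward mode", {
  mem <- membrane_state(v_m = -0.18)
  ex <- std_ex()
  ions <- ion_state(ca_mito = 1e-7, ca_cyt = 1e-7)
  expect_lt(cycle_free_energy(ions, mem, ex), 0)
  expect_gt(ncx_flux(ions, mem, ex), 0)
})

test_that("a cytosolic spike against a resting matrix imports Ca2+", {
  flux <- ncx_flux(ion_state(ca_mito = 1e-7, ca_cyt = 1.5e-5),
                   std_mem(), std_ex())
  expect_lt(flux, 0)
})

test_that("flux sign always opposes the cycle free energy", {
  states <- random_states(1000, seed = 42)
  for (st in states) {
    f <- ncx_flux(st$ions, st$mem, st$params)
    dg <- cycle_free_energy(st$ions, st$mem, st$params)
    expect_identical(sign(f), -sign(dg))
  }
})

test_that("flux is bounded by the turnover scale", {
  states <- random_states(500, seed = 7)
  for (st in states) {
    expect_lte(abs(ncx_flux(st$ions, st$mem, st$params)),
               st$params$k_turnover)
  }
  # extreme polarisation as well
  for (v in c(-0.3, -0.18, 0.3)) {
    f <- ncx_flux(ion_state(1e-4, 1e-9), membrane_state(v), std_ex())
    expect_lte(abs(f), std_ex()$k_turnover)
  }
})

test_that("flux is monotone in each concentration and in voltage", {
  ex <- std_ex()
  mem <- std_mem()
  base <- list(ca_mito = 1e-7, ca_cyt = 5e-7, na_mito = 4.54e-3,
               na_cyt = 10e-3)
  f0 <- ncx_flux(do.call(ion_state, base), mem, ex)
  bump <- function(field, factor) {
    b <- base
    b[[field]] <- b[[field]] * factor
    ncx_flux(do.call(ion_state, b), mem, ex)
  }
  expect_gt(bump("ca_mito", 1.5), f0)   # more matrix Ca2+ -> more export
  expect_lt(bump("ca_cyt", 1.5), f0)    # more cytosolic Ca2+ -> less
  expect_gt(bump("na_cyt", 1.5), f0)
  expect_lt(bump("na_mito", 1.5), f0)
  # hyperpolarisation favours export for n > 2
  f_hyper <- ncx_flux(do.call(ion_state, base),
                      membrane_state(v_m = -0.1), ex)
  expect_gt(f_hyper, f0)
})

test_that("electroneutral stoichiometry removes the voltage dependence", {
  # n = 2 is outside the public electrogenic contract; probe the core law
  p <- std_ex()
  p$n_na <- 2L
  f <- vapply(c(-0.18, -0.02, 0, 0.05), function(v) {
    mitoncx:::.ncx_flux_core(1e-7, 5e-7, 4.54e-3, 10e-3, v, 298, p)
  }, numeric(1))
  expect_true(all(abs(f - f[1]) < 1e-15 * abs(f[1])))
})

test_that("activation gate has the Hill form and saturates at one", {
  off <- std_ex()
  expect_identical(activation_factor(1e-9, off), 1)
  on <- std_ex(activation_enabled = TRUE, k_act = 5e-8, h_act = 4)
  expect_equal(activation_factor(5e-8, on), 0.5)
  expect_lt(activation_factor(1e-10, on), 1e-8)
  x <- 10^seq(-10, -5, length.out = 50)
  a <- activation_factor(x, on)
  expect_true(all(diff(a) > 0))
  expect_true(all(a >= 0 & a <= 1))
  # gating scales the flux without moving the reversal point
  eq <- std_equilibrium(1e-7, std_mem(), on)
  expect_lt(abs(ncx_flux(ion_state(eq, 1e-7), std_mem(), on)),
            1e-12 * on$k_turnover)
})
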