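# Single-exchanger Na+-Ca2+ flux law: thermodynamics, reversal point,
# optional matrix-Ca2+ activation gate.

#' Ion concentrations on both faces of the inner mitochondrial membrane
#'
#' Bundles the four free ion concentrations that the single-exchanger flux
#' law depends on. All concentrations are molar and must be strictly
#' positive (logarithms of ratios are taken downstream).
#'
#' @param ca_mito Free matrix Ca2+ concentration (M).
#' @param ca_cyt Cytosolic free Ca2+ concentration (M).
#' @param na_mito Matrix Na+ concentration (M). Default 4.54 mM.
#' @param na_cyt Cytosolic Na+ concentration (M). Default 10 mM.
#' @return An object of class `ion_state`.
#' @examples
#' ion_state(ca_mito = 1e-7, ca_cyt = 1e-7)
#' @export
ion_state <- function(ca_mito, ca_cyt, na_mito = 4.54e-3, na_cyt = 10e-3) {
  x <- list(ca_mito = ca_mito, ca_cyt = ca_cyt,
            na_mito = na_mito, na_cyt = na_cyt)
  for (nm in names(x)) {
    v <- x[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("`", nm, "` must be a single finite concentration > 0 (molar)",
           call. = FALSE)
    }
  }
  structure(x, class = "ion_state")
}

#' Inner-membrane electrical state
#'
#' @param v_m Inner-membrane potential, matrix minus cytosol (V). Negative
#'   when the mitochondrion is energised. Default -20 mV, the depolarised
#'   (FCCP-treated) regime.
#' @param temperature Absolute temperature (K). Default 298 K.
#' @return An object of class `membrane_state`.
#' @examples
#' membrane_state()                 # depolarised, -20 mV
#' membrane_state(v_m = -0.18)     # energised
#' @export
membrane_state <- function(v_m = -0.02, temperature = 298) {
  if (!is.numeric(v_m) || length(v_m) != 1L || !is.finite(v_m) ||
      abs(v_m) >= 0.5) {
    stop("`v_m` must be a single membrane potential with |v_m| < 0.5 V",
         call. = FALSE)
  }
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature) || temperature <= 0) {
    stop("`temperature` must be a single value > 0 K", call. = FALSE)
  }
  structure(list(v_m = v_m, temperature = temperature),
            class = "membrane_state")
}

#' Kinetic and stoichiometric parameters of the exchanger
#'
#' The flux law is a reduced, thermodynamically consistent carrier model: an
#' Eyring-factored mass-action numerator over a saturating denominator, so
#' that net flux vanishes exactly where the per-cycle free energy vanishes
#' and its magnitude never exceeds `k_turnover`. An optional Hill-type
#' activation gate on matrix Ca2+ represents the requirement for a small
#' matrix Ca2+ rise (ionomycin trigger) before reverse-mode transport runs.
#'
#' @param n_na Integer count of Na+ ions countertransported per Ca2+ per
#'   cycle. Must be > 2 (electrogenic operation). Default 3, the most widely
#'   cited stoichiometry.
#' @param k_turnover Flux scale: ions Ca2+ per second through one exchanger
#'   at saturation. The default is calibrated so that 100 exchangers with
#'   matrix buffering 100 carry matrix free Ca2+ across >= 90% of the gap
#'   between baseline and spike reversal points within a 20-s spike of a
#'   15 uM square-wave drive (see [calibrate_turnover()]).
#' @param k_ca Ca2+ half-saturation constant (M). Default 10 uM.
#' @param k_na Na+ half-saturation constant (M). Default 8 mM.
#' @param activation_enabled Logical; gate the flux by matrix Ca2+?
#'   Default `FALSE` (the plain flux law).
#' @param k_act Activation half-point (M free matrix Ca2+). Default 50 nM.
#' @param h_act Activation Hill coefficient (>= 1). Default 4: the gate
#'   must be steep enough that the resting matrix (well below `k_act`)
#'   cannot bootstrap itself into oscillation without a preload.
#' @return An object of class `exchanger_params`.
#' @examples
#' exchanger_params()
#' exchanger_params(activation_enabled = TRUE)
#' @export
exchanger_params <- function(n_na = 3L, k_turnover = 2030, k_ca = 1e-5,
                             k_na = 8e-3, activation_enabled = FALSE,
                             k_act = 5e-8, h_act = 4) {
  if (!is.numeric(n_na) || length(n_na) != 1L || n_na != round(n_na) ||
      n_na <= 2) {
    stop("`n_na` must be an integer > 2 (electrogenic stoichiometry)",
         call. = FALSE)
  }
  for (nm in c("k_turnover", "k_ca", "k_na", "k_act")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("`", nm, "` must be a single value > 0", call. = FALSE)
    }
  }
  if (!is.numeric(h_act) || length(h_act) != 1L || h_act < 1) {
    stop("`h_act` must be >= 1", call. = FALSE)
  }
  structure(list(n_na = as.integer(n_na), k_turnover = k_turnover,
                 k_ca = k_ca, k_na = k_na,
                 activation_enabled = isTRUE(activation_enabled),
                 k_act = k_act, h_act = h_act),
            class = "exchanger_params")
}

#' @export
print.exchanger_params <- function(x, ...) {
  cat("Na+-Ca2+ exchanger parameters\n")
  cat(sprintf("  stoichiometry : %d Na+ : 1 Ca2+ per cycle\n", x$n_na))
  cat(sprintf("  k_turnover    : %g ions/s at saturation\n", x$k_turnover))
  cat(sprintf("  K_Ca, K_Na    : %g M, %g M\n", x$k_ca, x$k_na))
  if (x$activation_enabled) {
    cat(sprintf("  matrix-Ca gate: on (K_act = %g M, Hill %g)\n",
                x$k_act, x$h_act))
  } else {
    cat("  matrix-Ca gate: off\n")
  }
  invisible(x)
}

#' Free energy of one forward exchange cycle
#'
#' A forward cycle moves `n_na` Na+ ions from cytosol to matrix and one Ca2+
#' ion from matrix to cytosol, translocating `n_na - 2` elementary charges
#' into the matrix:
#' \deqn{\Delta G = n RT \ln([Na]_m/[Na]_c) + RT \ln([Ca]_c/[Ca]_m)
#'   + (n-2) F V_m.}
#' Negative values favour forward (Ca2+-export) operation; net flux always
#' has the opposite sign of this quantity.
#'
#' @param ions An [ion_state()].
#' @param mem A [membrane_state()].
#' @param params An [exchanger_params()] (only the stoichiometry is used).
#' @return Free energy per mole of forward cycles (J/mol).
#' @examples
#' cycle_free_energy(ion_state(1e-7, 1e-7), membrane_state(-0.18, 298),
#'                   exchanger_params())
#' @export
cycle_free_energy <- function(ions, mem, params) {
  stopifnot(inherits(ions, "ion_state"), inherits(mem, "membrane_state"),
            inherits(params, "exchanger_params"))
  n <- params$n_na
  rt <- .GAS_R * mem$temperature
  n * rt * log(ions$na_mito / ions$na_cyt) +
    rt * log(ions$ca_cyt / ions$ca_mito) +
    (n - 2) * .FARADAY * mem$v_m
}

#' Matrix Ca2+ concentration at the exchanger's reversal point
#'
#' Closed-form zero of the net flux: the matrix free Ca2+ level at which the
#' Na+ gradient, the Ca2+ gradient and the membrane potential balance,
#' \deqn{[Ca]_m^* = [Ca]_c \,([Na]_m/[Na]_c)^n\, e^{(n-2) F V_m / RT}.}
#' Above this level the exchanger exports Ca2+ (forward mode); below it,
#' with sufficient cytosolic Ca2+, it imports (reverse mode). Each phase of
#' an oscillating cytosolic drive drags the matrix toward its own reversal
#' point, which is what makes the matrix oscillate.
#'
#' @param ca_cyt Cytosolic free Ca2+ (M); may be a vector.
#' @param na_mito,na_cyt Na+ concentrations (M).
#' @param mem A [membrane_state()].
#' @param params An [exchanger_params()].
#' @return Matrix free Ca2+ at zero net flux (M), same length as `ca_cyt`.
#' @examples
#' # Depolarised resting conditions: ~4.3 nM
#' equilibrium_matrix_ca(1e-7, 4.54e-3, 10e-3, membrane_state(),
#'                       exchanger_params())
#' @export
equilibrium_matrix_ca <- function(ca_cyt, na_mito, na_cyt, mem, params) {
  stopifnot(inherits(mem, "membrane_state"),
            inherits(params, "exchanger_params"))
  if (any(!is.finite(ca_cyt)) || any(ca_cyt <= 0) ||
      !is.finite(na_mito) || na_mito <= 0 ||
      !is.finite(na_cyt) || na_cyt <= 0) {
    stop("concentrations must be finite and > 0", call. = FALSE)
  }
  n <- params$n_na
  ca_cyt * (na_mito / na_cyt)^n *
    exp((n - 2) * .FARADAY * mem$v_m / (.GAS_R * mem$temperature))
}

#' Matrix-Ca2+ activation factor of the exchanger
#'
#' Hill gate in \[0, 1\]: `ca_mito^h / (ca_mito^h + k_act^h)` when the gate
#' is enabled, 1 otherwise. With the gate on and resting matrix Ca2+ well
#' below `k_act` the exchanger is nearly silent; a small matrix preload
#' (e.g. low-dose ionomycin) releases it.
#'
#' @param ca_mito Free matrix Ca2+ (M); may be a vector.
#' @param params An [exchanger_params()].
#' @return Dimensionless factor(s) in \[0, 1\].
#' @examples
#' activation_factor(5e-8, exchanger_params(activation_enabled = TRUE))
#' @export
activation_factor <- function(ca_mito, params) {
  stopifnot(inherits(params, "exchanger_params"))
  if (any(!is.finite(ca_mito)) || any(ca_mito <= 0)) {
    stop("`ca_mito` must be finite and > 0", call. = FALSE)
  }
  if (!params$activation_enabled) {
    return(rep(1, length(ca_mito)))
  }
  xh <- (ca_mito / params$k_act)^params$h_act
  xh / (xh + 1)
}

# Vectorised core of the flux law; no class checks, used inside the ODE
# right-hand side. Arguments are plain numerics (ca_mito and/or ca_cyt may
# be vectors of equal or broadcastable length).
.ncx_flux_core <- function(ca_mito, ca_cyt, na_mito, na_cyt, v_m,
                           temperature, params) {
  n <- params$n_na
  theta <- (n - 2) * .FARADAY * v_m / (2 * .GAS_R * temperature)
  ep <- exp(theta)
  em <- exp(-theta)
  num <- na_cyt^n * ca_mito * em - na_mito^n * ca_cyt * ep
  den <- (params$k_na^n + na_cyt^n) * (params$k_ca + ca_mito) * em +
         (params$k_na^n + na_mito^n) * (params$k_ca + ca_cyt) * ep
  act <- if (params$activation_enabled) {
    xh <- (ca_mito / params$k_act)^params$h_act
    xh / (xh + 1)
  } else 1
  act * params$k_turnover * num / den
}

#' Net Ca2+ flux through a single exchanger
#'
#' Reduced carrier model of electrogenic Na+-Ca2+ exchange. The numerator
#' is the mass-action difference of the two cycle directions with a
#' symmetric Eyring voltage split; the denominator is a strictly positive
#' saturating term carrying the same voltage factors, so that
#' `|flux| <= k_turnover` for every admissible state and the flux changes
#' sign exactly at the reversal point given by [equilibrium_matrix_ca()]
#' (equivalently, where [cycle_free_energy()] is zero).
#'
#' Sign convention: positive flux is Ca2+ export from the matrix (forward
#' mode); negative flux is Ca2+ import (reverse mode).
#'
#' @param ions An [ion_state()].
#' @param mem A [membrane_state()].
#' @param params An [exchanger_params()].
#' @return Net flux in Ca2+ ions per second through one exchanger.
#' @examples
#' # Cytosolic spike against a resting matrix: reverse mode (negative)
#' ncx_flux(ion_state(ca_mito = 1e-7, ca_cyt = 1.5e-5),
#'          membrane_state(), exchanger_params())
#' @export
ncx_flux <- function(ions, mem, params) {
  stopifnot(inherits(ions, "ion_state"), inherits(mem, "membrane_state"),
            inherits(params, "exchanger_params"))
  .ncx_flux_core(ions$ca_mito, ions$ca_cyt, ions$na_mito, ions$na_cyt,
                 mem$v_m, mem$temperature, params)
}
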