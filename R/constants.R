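# Physical constants (SI). CODATA 2018 values.

#' Physical constants used throughout the package
#'
#' Faraday constant (C/mol), molar gas constant (J/mol/K) and Avogadro's
#' number (1/mol), as a named list. Exposed so that scripts can reproduce
#' hand calculations with exactly the constants the package uses.
#'
#' @return Named list with elements `faraday`, `gas` and `avogadro`.
#' @examples
#' physical_constants()$faraday
#' @export
physical_constants <- function() {
  list(
    faraday  = 96485.33212,
    gas      = 8.31446261815324,
    avogadro = 6.02214076e23
  )
}

.FARADAY  <- 96485.33212
.GAS_R    <- 8.31446261815324
.AVOGADRO <- 6.02214076e23
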