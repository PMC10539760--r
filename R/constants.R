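## Physical constants used throughout; all energies in kcal/mol, rates in 1/s.

#' Gas constant in kcal/(mol K)
#'
#' The value used for every Boltzmann factor, Arrhenius regression and Eyring
#' conversion in the package, so that energies are in kcal/mol and
#' temperatures in K.
#'
#' @format Numeric scalar, 1.9872e-3 kcal/(mol K).
#' @export
GAS_CONSTANT_KCAL <- 1.9872e-3

## Boltzmann constant over Planck constant, 1/(K s); kB*T/h is the Eyring
## attempt frequency (2.0837e10 * T).
.kB_over_h <- 1.380649e-23 / 6.62607015e-34

## internal: wrap angles in degrees to the half-open interval [-180, 180)
.wrapDeg <- function(x) {
  w <- (x + 180) %% 360 - 180
  ## %% can return 360 - eps + (-180) == 180 for tiny negative residuals
  w[w >= 180] <- w[w >= 180] - 360
  w
}

.isScalarNumber <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
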