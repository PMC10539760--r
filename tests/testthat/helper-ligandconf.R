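## shared fixtures for the test suite

## the standard eight-point mixing-time schedule, s
MIX_TIMES <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.7, 1, 2)

## trapezoid integral of a Spectrum
trapz <- function(sp) {
  f <- sp@freq
  y <- sp@intensity
  sum(diff(f) * (y[-length(y)] + y[-1]) / 2)
}

## symmetric 1:1 exchange system builder, rate given as the chemist's
## first-order rate constant k (kEx = 2k)
symSystem <- function(k, deltaNu = 100, r2 = pi * 2) {
  ExchangeSystem(pA = 0.5, nuA = -deltaNu / 2, nuB = deltaNu / 2,
                 r2A = r2, r2B = r2, kEx = 2 * k)
}
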