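## Selective-EXSY kinetics: normalization, build-up models, rate fits,
## Arrhenius and Eyring barrier conversions, exchange-regime classification.

#' Normalize EXSY integrals
#'
#' Calibrates the integral of the selectively inverted (reference) peak to
#' 100 and expresses the exchanged peak on the same scale; the fractional
#' intensity increase is exchanged/reference. Homogeneous: scaling both raw
#' integrals by a common factor leaves the output unchanged.
#'
#' @param rawReference raw integral of the inverted reference peak (nonzero)
#' @param rawExchanged raw integral of the exchanged peak
#' @return list with \code{reference} (100), \code{exchanged} (scaled) and
#'   \code{fraction} (exchanged/reference)
#' @examples
#' normalizeIntegrals(200, 50) # exchanged 25, fraction 0.25
#' @export
normalizeIntegrals <- function(rawReference, rawExchanged) {
  if (any(rawReference == 0)) stop("reference integral must be nonzero")
  list(reference = 100,
       exchanged = 100 * rawExchanged / rawReference,
       fraction = rawExchanged / rawReference)
}

#' Equal-population two-site EXSY build-up model
#'
#' Fractional intensity increase of the exchanged peak after mixing time
#' tau for a 1:1 exchanging pair with first-order rate constant k:
#' \code{f(tau) = 0.5 * (1 - exp(-2 k tau))}, approaching the equilibrium
#' value 1/2. With a longitudinal relaxation time \code{t1}, the same
#' expression is damped by \code{exp(-tau / t1)}.
#'
#' @param k first-order exchange rate constant, 1/s (>= 0)
#' @param tau mixing time(s), s (>= 0)
#' @param t1 optional longitudinal relaxation time, s
#' @return fractional intensity increase
#' @examples
#' buildupModel(1.386, 0.5) # ~0.375
#' @export
buildupModel <- function(k, tau, t1 = NULL) {
  if (any(k < 0)) stop("k must be >= 0")
  if (any(tau < 0)) stop("mixing times must be >= 0")
  f <- 0.5 * (1 - exp(-2 * k * tau))
  if (!is.null(t1)) {
    if (t1 <= 0) stop("t1 must be > 0")
    f <- f * exp(-tau / t1)
  }
  f
}

#' Unequal-population two-site build-up model
#'
#' Generalization \code{f(tau) = pB * (1 - exp(-kEx * tau))} for an
#' exchanging pair with populations (pA, pB) and total exchange rate kEx;
#' reduces to \code{\link{buildupModel}} with \code{kEx = 2k} when
#' \code{pB = 0.5}.
#'
#' @param kEx total exchange rate constant kAB + kBA, 1/s
#' @param tau mixing time(s), s
#' @param pB population of the exchanged site
#' @param t1 optional longitudinal relaxation time, s
#' @return fractional intensity increase
#' @export
buildupModelUnequal <- function(kEx, tau, pB, t1 = NULL) {
  if (any(kEx < 0)) stop("kEx must be >= 0")
  if (any(tau < 0)) stop("mixing times must be >= 0")
  if (pB < 0 || pB > 1) stop("pB must lie in [0, 1]")
  f <- pB * (1 - exp(-kEx * tau))
  if (!is.null(t1)) f <- f * exp(-tau / t1)
  f
}

## internal: residual sum of squares of the build-up model on a curve
.buildupSS <- function(k, tau, y, t1) sum((y - buildupModel(k, tau, t1)) ^ 2)

#' Fit a first-order exchange rate to a build-up curve
#'
#' Nonlinear least squares of the equal-population build-up model to a
#' normalized EXSY curve. The single parameter k is found by a coarse
#' logarithmic bracket followed by golden-section refinement, with k >= 0
#' enforced; this cannot fail to converge on the bracket, and an explicit
#' \code{converged} flag is carried rather than silent failure. All-zero
#' intensities return k = 0 with the no-exchange flag set.
#'
#' @param curve data.frame with columns \code{mixing_time_s} and
#'   \code{intensity} (at least 3 points), e.g. from \code{\link{exsyCurve}}
#' @param modelTag "no-t1" (default; pure first-order kinetics) or "t1"
#'   (build-up damped by longitudinal relaxation, requires \code{t1})
#' @param t1 longitudinal relaxation time, s, for \code{modelTag = "t1"}
#' @param temperature temperature label stored in the fit, K
#' @return a \linkS4class{RateFit}
#' @examples
#' tau <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.7, 1, 2)
#' fit <- fitRate(data.frame(mixing_time_s = tau,
#'                           intensity = buildupModel(1.5, tau)))
#' exchangeRate(fit)
#' @export
fitRate <- function(curve, modelTag = c("no-t1", "t1"), t1 = NULL,
                    temperature = NA_real_) {
  modelTag <- match.arg(modelTag)
  if (!all(c("mixing_time_s", "intensity") %in% names(curve)))
    stop("curve must have columns mixing_time_s and intensity")
  tau <- curve$mixing_time_s
  y <- curve$intensity
  if (length(tau) < 3) stop("at least 3 mixing-time points are required")
  if (any(tau <= 0)) stop("mixing times must be > 0")
  if (any(diff(tau) <= 0)) stop("mixing times must be strictly increasing")
  t1fit <- if (modelTag == "t1") {
    if (is.null(t1)) stop("modelTag 't1' requires a t1 value")
    t1
  } else NULL
  if (all(y == 0)) {
    return(new("RateFit", k = 0, tHalf = Inf, residualSS = 0,
               modelTag = modelTag, temperature = temperature,
               converged = TRUE, noExchange = TRUE))
  }
  ## coarse logarithmic scan brackets the minimum, then golden-section refine
  kGrid <- c(0, 10 ^ seq(-4, 4, length.out = 81))
  ss <- vapply(kGrid, .buildupSS, numeric(1), tau = tau, y = y, t1 = t1fit)
  i <- which.min(ss)
  lo <- kGrid[max(1, i - 1)]
  hi <- if (i == length(kGrid)) kGrid[i] * 10 else kGrid[i + 1]
  opt <- stats::optimize(.buildupSS, c(lo, hi), tau = tau, y = y, t1 = t1fit,
                         tol = 1e-12)
  ## one Newton polish for full precision on smooth noiseless curves
  k <- opt$minimum
  for (it in 1:4) {
    h <- max(1e-7, 1e-7 * k)
    g <- (.buildupSS(k + h, tau, y, t1fit) -
          .buildupSS(k - h, tau, y, t1fit)) / (2 * h)
    H <- (.buildupSS(k + h, tau, y, t1fit) - 2 * .buildupSS(k, tau, y, t1fit) +
          .buildupSS(k - h, tau, y, t1fit)) / h ^ 2
    if (!is.finite(g) || !is.finite(H) || H <= 0) break
    kNew <- max(0, k - g / H)
    if (.buildupSS(kNew, tau, y, t1fit) <= .buildupSS(k, tau, y, t1fit))
      k <- kNew else break
  }
  new("RateFit", k = k, tHalf = if (k > 0) log(2) / k else Inf,
      residualSS = .buildupSS(k, tau, y, t1fit), modelTag = modelTag,
      temperature = temperature, converged = TRUE, noExchange = FALSE)
}

#' @rdname fitRate
#' @param fit a \linkS4class{RateFit}
#' @export
exchangeRate <- function(fit) {
  stopifnot(is(fit, "RateFit"))
  fit@k
}

#' @rdname fitRate
#' @export
halfLife <- function(fit) {
  stopifnot(is(fit, "RateFit"))
  fit@tHalf
}

#' Fit rates for every curve of an EXSY dataset
#'
#' @param dataset an \linkS4class{EXSYDataset}
#' @param ... passed to \code{\link{fitRate}}
#' @return list of \linkS4class{RateFit}, one per temperature (ascending)
#' @export
fitRates <- function(dataset, ...) {
  stopifnot(is(dataset, "EXSYDataset"))
  temps <- exsyTemperatures(dataset)
  fits <- lapply(temps, function(T)
    fitRate(exsyCurve(dataset, T), temperature = T, ...))
  names(fits) <- as.character(temps)
  fits
}

#' Arrhenius fit of rate constants
#'
#' Ordinary least squares of ln(k) against 1/(R*T) (R in kcal/(mol K)), so
#' the slope is minus the activation energy and the intercept is ln(A)
#' directly. A warning is emitted when the temperature span is narrower than
#' \code{minSpanK}: barriers extrapolated from a narrow span are poorly
#' conditioned against rate noise.
#'
#' @param rates data.frame with columns \code{temperature_K} and \code{k}
#'   (all > 0; >= 2 distinct temperatures), or a list of
#'   \linkS4class{RateFit} from \code{\link{fitRates}}
#' @param minSpanK span (K) below which the narrow-span warning fires
#' @return an \linkS4class{ArrheniusFit}
#' @examples
#' truth <- arrheniusTruth(ea = 19.9, kRef = 1.386, tRef = 300)
#' k <- arrheniusRate(truth, c(300, 305, 310))
#' fit <- suppressWarnings(
#'   fitArrhenius(data.frame(temperature_K = c(300, 305, 310), k = k)))
#' activationEnergy(fit)
#' @export
fitArrhenius <- function(rates, minSpanK = 20) {
  if (is.list(rates) && length(rates) && is(rates[[1]], "RateFit")) {
    rates <- data.frame(
      temperature_K = vapply(rates, function(f) f@temperature, numeric(1)),
      k = vapply(rates, function(f) f@k, numeric(1)))
  }
  if (!all(c("temperature_K", "k") %in% names(rates)))
    stop("rates must have columns temperature_K and k")
  if (any(rates$k <= 0)) stop("all rate constants must be > 0")
  if (anyDuplicated(rates$temperature_K)) stop("duplicate temperature")
  if (nrow(rates) < 2) stop("at least 2 distinct temperatures are required")
  x <- 1 / (GAS_CONSTANT_KCAL * rates$temperature_K)
  fit <- stats::lm(log(rates$k) ~ x)
  ea <- -unname(stats::coef(fit)[2])
  lnA <- unname(stats::coef(fit)[1])
  ## suppressWarnings: summary.lm flags essentially perfect (collinear) fits
  r2 <- if (nrow(rates) > 2) suppressWarnings(summary(fit)$r.squared) else 1
  narrow <- diff(range(rates$temperature_K)) < minSpanK
  if (narrow)
    warning(sprintf(paste0("temperature span %.0f K is narrow (< %.0f K); ",
                           "the extrapolated barrier is sensitive to rate ",
                           "noise"),
                    diff(range(rates$temperature_K)), minSpanK))
  new("ArrheniusFit", ea = ea, lnA = lnA,
      rates = rates[order(rates$temperature_K), ], rSquared = r2,
      narrowSpan = narrow)
}

#' @rdname fitArrhenius
#' @param fit an \linkS4class{ArrheniusFit}
#' @export
activationEnergy <- function(fit) {
  stopifnot(is(fit, "ArrheniusFit"))
  fit@ea
}

#' Eyring conversions between rate and free-energy barrier
#'
#' Transition-state relation with transmission coefficient 1:
#' \code{k = (kB*T/h) * exp(-dG/(R*T))}, so
#' \code{dG = R*T*log(kB*T/(h*k))}. \code{eyringBarrier} and
#' \code{eyringRate} are mutual inverses; the barrier is strictly decreasing
#' in k at fixed temperature.
#'
#' @param k rate constant, 1/s (> 0)
#' @param temperature temperature, K (> 0)
#' @return \code{eyringBarrier}: free-energy barrier, kcal/mol
#' @examples
#' eyringBarrier(log(2) / 0.5, 300)  # ~17.4 kcal/mol (0.5 s half-life)
#' eyringBarrier(log(2) / 1e-9, 300) # ~5.4 kcal/mol (ns half-life)
#' @export
eyringBarrier <- function(k, temperature) {
  if (any(k <= 0)) stop("k must be > 0")
  if (any(temperature <= 0)) stop("temperature must be > 0")
  GAS_CONSTANT_KCAL * temperature * log(.kB_over_h * temperature / k)
}

#' @rdname eyringBarrier
#' @param dG free-energy barrier, kcal/mol
#' @return \code{eyringRate}: rate constant, 1/s
#' @export
eyringRate <- function(dG, temperature) {
  if (any(temperature <= 0)) stop("temperature must be > 0")
  .kB_over_h * temperature * exp(-dG / (GAS_CONSTANT_KCAL * temperature))
}

#' Classify the NMR exchange regime
#'
#' Compares the first-order rate constant k with the coalescence rate
#' \code{k_c = pi * delta_nu / sqrt(2)}: "slow" below k_c/10, "fast" above
#' 10*k_c, otherwise "intermediate".
#'
#' @param k first-order exchange rate constant, 1/s
#' @param deltaNu frequency separation of the exchanging signals, Hz (> 0)
#' @return one of "slow", "intermediate", "fast"
#' @examples
#' classifyExchangeRegime(1.386, 100) # slow (0.5 s half-life, doubled peaks)
#' classifyExchangeRegime(1e9, 100)   # fast (ns half-life, sharp averaged line)
#' @export
classifyExchangeRegime <- function(k, deltaNu) {
  kc <- coalescenceRate(deltaNu)
  ifelse(k < kc / 10, "slow", ifelse(k > 10 * kc, "fast", "intermediate"))
}

#' Read / write EXSY datasets as CSV
#'
#' Long format with columns \code{temperature_K}, \code{mixing_time_s},
#' \code{intensity}; provenance travels separately (JSON) when needed.
#'
#' @param dataset an \linkS4class{EXSYDataset}
#' @param path file path
#' @return \code{writeEXSYCsv}: the path, invisibly;
#'   \code{readEXSYCsv}: an \linkS4class{EXSYDataset}
#' @export
writeEXSYCsv <- function(dataset, path) {
  stopifnot(is(dataset, "EXSYDataset"))
  utils::write.csv(dataset@data, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEXSYCsv
#' @export
readEXSYCsv <- function(path) {
  d <- utils::read.csv(path)
  d <- d[order(d$temperature_K, d$mixing_time_s), ]
  rownames(d) <- NULL
  EXSYDataset(d)
}
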