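#' @import methods
NULL

## ---------------------------------------------------------------------------
## Two-site exchange

#' Two-site chemical-exchange spin system
#'
#' Parameters of a spin exchanging between two magnetically inequivalent
#' sites A and B, e.g. the two rotamers of a hindered bond. The total
#' exchange rate \code{kEx} is the sum of the forward and backward rate
#' constants, with detailed balance \code{kAB * pA == kBA * pB} so that
#' \code{kAB = pB * kEx} and \code{kBA = pA * kEx}. For a 1:1 rotamer pair
#' the first-order rate constant measured by EXSY is \code{kEx / 2}.
#'
#' @slot pA,pB site populations (molar fractions, sum to 1)
#' @slot nuA,nuB site frequencies in Hz
#' @slot r2A,r2B intrinsic transverse relaxation rates in 1/s; the
#'   no-exchange full width at half maximum of a site is \code{r2 / pi} Hz
#' @slot kEx total exchange rate constant kAB + kBA, 1/s
#' @export
setClass("ExchangeSystem",
  representation(pA = "numeric", pB = "numeric", nuA = "numeric",
                 nuB = "numeric", r2A = "numeric", r2B = "numeric",
                 kEx = "numeric"),
  validity = function(object) {
    msg <- character()
    for (s in c("pA", "pB", "nuA", "nuB", "r2A", "r2B", "kEx"))
      if (!.isScalarNumber(slot(object, s)))
        msg <- c(msg, sprintf("'%s' must be a finite numeric scalar", s))
    if (length(msg)) return(msg)
    if (object@pA < 0 || object@pB < 0)
      msg <- c(msg, "populations must be non-negative")
    if (abs(object@pA + object@pB - 1) > 1e-12)
      msg <- c(msg, "pA + pB must equal 1 (within 1e-12)")
    if (object@r2A <= 0 || object@r2B <= 0)
      msg <- c(msg, "R2 rates must be positive")
    if (object@kEx < 0)
      msg <- c(msg, "kEx must be non-negative")
    if (length(msg)) msg else TRUE
  })

#' Construct a two-site exchange system
#'
#' Site positions may be given in Hz, or in ppm together with an explicit
#' spectrometer frequency (never implicit) in which case they are converted
#' to Hz via \code{nu = ppm * frequencyMHz}.
#'
#' @param pA population of site A; \code{pB = 1 - pA}
#' @param nuA,nuB site frequencies (Hz, or ppm when \code{ppm = TRUE})
#' @param r2A,r2B transverse relaxation rates, 1/s
#' @param kEx total exchange rate constant (kAB + kBA), 1/s
#' @param ppm interpret \code{nuA}, \code{nuB} as ppm
#' @param frequencyMHz spectrometer frequency, MHz; required when
#'   \code{ppm = TRUE}
#' @return an \linkS4class{ExchangeSystem}
#' @examples
#' ExchangeSystem(pA = 0.5, nuA = -50, nuB = 50, r2A = pi * 2.8,
#'                r2B = pi * 2.8, kEx = 1)
#' @export
ExchangeSystem <- function(pA = 0.5, nuA, nuB, r2A, r2B = r2A, kEx = 0,
                           ppm = FALSE, frequencyMHz = NULL) {
  if (ppm) {
    if (is.null(frequencyMHz))
      stop("ppm input requires an explicit 'frequencyMHz'")
    nuA <- nuA * frequencyMHz
    nuB <- nuB * frequencyMHz
  }
  new("ExchangeSystem", pA = pA, pB = 1 - pA, nuA = nuA, nuB = nuB,
      r2A = r2A, r2B = r2B, kEx = kEx)
}

#' 1D absorption spectrum
#'
#' @slot freq monotone increasing frequency axis, Hz
#' @slot intensity non-negative absorption values, same length as \code{freq}
#' @export
setClass("Spectrum",
  representation(freq = "numeric", intensity = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@freq) != length(object@intensity))
      msg <- c(msg, "freq and intensity must have equal length")
    if (length(object@freq) > 1 && any(diff(object@freq) <= 0))
      msg <- c(msg, "freq must be strictly increasing")
    if (any(!is.finite(object@intensity)))
      msg <- c(msg, "intensity must be finite")
    if (length(msg)) msg else TRUE
  })

#' @rdname Spectrum-class
#' @param freq,intensity numeric vectors of equal length
#' @export
Spectrum <- function(freq, intensity) {
  new("Spectrum", freq = as.numeric(freq), intensity = as.numeric(intensity))
}

## ---------------------------------------------------------------------------
## EXSY kinetics

#' Arrhenius ground truth for synthetic rate generation
#'
#' @slot ea activation energy, kcal/mol
#' @slot lnA natural log of the pre-exponential factor (A in 1/s)
#' @slot temperatures strictly increasing temperatures, K
#' @export
setClass("ArrheniusTruth",
  representation(ea = "numeric", lnA = "numeric", temperatures = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!.isScalarNumber(object@ea) || object@ea <= 0)
      msg <- c(msg, "ea must be a positive scalar")
    if (!.isScalarNumber(object@lnA))
      msg <- c(msg, "lnA must be a finite scalar")
    if (length(object@temperatures) < 1 || any(object@temperatures <= 0))
      msg <- c(msg, "temperatures must all be > 0 K")
    if (length(object@temperatures) > 1 &&
        any(diff(object@temperatures) <= 0))
      msg <- c(msg, "temperatures must be strictly increasing")
    if (length(msg)) msg else TRUE
  })

#' Construct Arrhenius ground truth
#'
#' Either give \code{lnA} directly, or anchor the law with a known rate
#' \code{kRef} at temperature \code{tRef}, from which
#' \code{lnA = log(kRef) + ea / (R * tRef)}.
#'
#' @param ea activation energy, kcal/mol
#' @param lnA log pre-exponential factor (1/s scale)
#' @param kRef,tRef anchor rate (1/s) and temperature (K), used when
#'   \code{lnA} is missing
#' @param temperatures temperatures (K) at which synthetic data are generated
#' @return an \linkS4class{ArrheniusTruth}
#' @examples
#' arrheniusTruth(ea = 19.9, kRef = 1.386, tRef = 300,
#'                temperatures = c(300, 305, 310))
#' @export
arrheniusTruth <- function(ea, lnA = NULL, kRef = NULL, tRef = 300,
                           temperatures = c(300, 305, 310)) {
  if (is.null(lnA)) {
    if (is.null(kRef))
      stop("supply either 'lnA' or an anchor rate 'kRef'")
    lnA <- log(kRef) + ea / (GAS_CONSTANT_KCAL * tRef)
  }
  new("ArrheniusTruth", ea = ea, lnA = lnA,
      temperatures = sort(as.numeric(temperatures)))
}

#' Arrhenius rate law
#'
#' @param truth an \linkS4class{ArrheniusTruth}
#' @param temperature temperature(s), K
#' @return rate constant(s) \code{exp(lnA - ea/(R*T))}, 1/s
#' @export
arrheniusRate <- function(truth, temperature) {
  stopifnot(is(truth, "ArrheniusTruth"))
  exp(truth@lnA - truth@ea / (GAS_CONSTANT_KCAL * temperature))
}

#' Variable-temperature EXSY build-up dataset
#'
#' One normalized build-up curve per temperature, stored long-format, with an
#' optional provenance block recording the generating ground truth.
#'
#' @slot data data.frame with columns \code{temperature_K},
#'   \code{mixing_time_s}, \code{intensity} (fractional intensity increase of
#'   the exchanged peak, reference peak calibrated to 100)
#' @slot provenance list of ground-truth parameters (possibly empty)
#' @export
setClass("EXSYDataset",
  representation(data = "data.frame", provenance = "list"),
  validity = function(object) {
    d <- object@data
    need <- c("temperature_K", "mixing_time_s", "intensity")
    if (!all(need %in% names(d)))
      return(paste("data must have columns", paste(need, collapse = ", ")))
    msg <- character()
    if (any(d$mixing_time_s <= 0))
      msg <- c(msg, "mixing times must be > 0")
    bad <- vapply(split(d$mixing_time_s, d$temperature_K),
                  function(x) any(diff(x) <= 0), logical(1))
    if (any(bad))
      msg <- c(msg, "mixing times must be strictly increasing per curve")
    if (length(msg)) msg else TRUE
  })

#' @rdname EXSYDataset-class
#' @param data long-format data.frame (see slots)
#' @param provenance optional ground-truth list
#' @export
EXSYDataset <- function(data, provenance = list()) {
  new("EXSYDataset", data = data, provenance = provenance)
}

#' Temperatures of an EXSY dataset
#' @param dataset an \linkS4class{EXSYDataset}
#' @return sorted unique temperatures, K
#' @export
exsyTemperatures <- function(dataset) {
  stopifnot(is(dataset, "EXSYDataset"))
  sort(unique(dataset@data$temperature_K))
}

#' Extract one build-up curve
#' @param dataset an \linkS4class{EXSYDataset}
#' @param temperature temperature, K (must match a stored curve)
#' @return data.frame with \code{mixing_time_s}, \code{intensity}
#' @export
exsyCurve <- function(dataset, temperature) {
  stopifnot(is(dataset, "EXSYDataset"))
  d <- dataset@data[dataset@data$temperature_K == temperature,
                    c("mixing_time_s", "intensity")]
  if (nrow(d) == 0)
    stop("no curve at temperature ", temperature, " K")
  rownames(d) <- NULL
  d
}

#' First-order exchange-rate fit of a build-up curve
#'
#' @slot k fitted first-order exchange rate constant, 1/s
#' @slot tHalf half-life ln(2)/k, s (Inf when k = 0)
#' @slot residualSS sum of squared residuals
#' @slot modelTag build-up model used ("no-t1" or "t1")
#' @slot temperature temperature of the fitted curve, K
#' @slot converged logical; FALSE signals an explicit failure state
#' @slot noExchange logical; TRUE when the curve carried no exchange signal
#' @export
setClass("RateFit",
  representation(k = "numeric", tHalf = "numeric", residualSS = "numeric",
                 modelTag = "character", temperature = "numeric",
                 converged = "logical", noExchange = "logical"),
  validity = function(object) {
    msg <- character()
    if (object@k < 0) msg <- c(msg, "k must be >= 0")
    if (object@residualSS < 0) msg <- c(msg, "residualSS must be >= 0")
    if (object@k > 0 && abs(object@tHalf - log(2) / object@k) > 1e-9)
      msg <- c(msg, "tHalf must equal ln(2)/k")
    if (length(msg)) msg else TRUE
  })

#' Arrhenius fit of rate constants
#'
#' Regression of ln(k) against 1/(R*T), so the slope is minus the activation
#' energy directly.
#'
#' @slot ea activation energy, kcal/mol
#' @slot lnA intercept, ln of the pre-exponential factor (1/s)
#' @slot rates data.frame(temperature_K, k) used in the fit
#' @slot rSquared coefficient of determination
#' @slot narrowSpan TRUE when the temperature span is narrow enough that the
#'   extrapolated barrier is poorly conditioned (a warning is also emitted)
#' @export
setClass("ArrheniusFit",
  representation(ea = "numeric", lnA = "numeric", rates = "data.frame",
                 rSquared = "numeric", narrowSpan = "logical"),
  validity = function(object) {
    if (nrow(object@rates) < 2)
      return("an Arrhenius fit needs >= 2 distinct temperatures")
    TRUE
  })

## ---------------------------------------------------------------------------
## Torsional sampling

#' Analytic torsional potential
#'
#' Cosine-series potential \eqn{V(\phi) = \sum_j (V_j/2)(1 + \cos(n_j \phi -
#' \gamma_j))} with \eqn{\phi} and \eqn{\gamma} in degrees and amplitudes in
#' kcal/mol; periodic with 360 degrees by construction.
#'
#' @slot terms data.frame with columns \code{n} (integer periodicity),
#'   \code{Vn} (amplitude, kcal/mol), \code{gamma} (phase, degrees)
#' @slot preset name of the generating preset, or "" for custom terms
#' @export
setClass("TorsionPotential",
  representation(terms = "data.frame", preset = "character"),
  validity = function(object) {
    t <- object@terms
    if (!all(c("n", "Vn", "gamma") %in% names(t)))
      return("terms must have columns n, Vn, gamma")
    if (nrow(t) < 1) return("at least one cosine term is required")
    if (any(t$n != round(t$n)) || any(t$n < 1))
      return("periodicities n must be positive integers")
    if (any(!is.finite(t$Vn)) || any(!is.finite(t$gamma)))
      return("amplitudes and phases must be finite")
    TRUE
  })

#' Replica-exchange torsional trajectory
#'
#' Output of \code{\link{runRex}}. Angles are stored per temperature slot
#' (column 1 = base temperature) and per sweep, wrapped to [-180, 180).
#'
#' @slot angles sweeps x replicas matrix of torsion angles, degrees
#' @slot walkers sweeps x replicas integer matrix; entry (s, i) is the id of
#'   the walker occupying temperature slot i after sweep s
#' @slot ladder replica temperatures, K, ascending, first = base
#' @slot exchangeLog data.frame(sweep, pair, accepted) of swap attempts
#'   between temperature slots pair and pair + 1
#' @slot seed,startAngle,stepDeg,exchangeInterval run configuration
#' @export
setClass("TorsionTrajectory",
  representation(angles = "matrix", walkers = "matrix", ladder = "numeric",
                 exchangeLog = "data.frame", seed = "numeric",
                 startAngle = "numeric", stepDeg = "numeric",
                 exchangeInterval = "numeric"),
  validity = function(object) {
    msg <- character()
    if (any(object@angles < -180 | object@angles >= 180))
      msg <- c(msg, "angles must lie in [-180, 180)")
    if (!all(dim(object@angles) == dim(object@walkers)))
      msg <- c(msg, "angles and walkers must have identical dimensions")
    if (ncol(object@angles) != length(object@ladder))
      msg <- c(msg, "one angle column per ladder temperature is required")
    if (length(msg)) msg else TRUE
  })

#' Torsion profile report
#'
#' Summary of a sampled torsion: analytic profile, base-temperature
#' histogram, located minima and barriers, per-well occupancies and the
#' ergodicity verdict.
#'
#' @slot profile data.frame(angle, V) of the analytic potential, kcal/mol
#' @slot histogram data.frame(mid, count) base-temperature histogram
#' @slot minima angles of the potential minima, degrees
#' @slot barriers min-to-saddle heights per well, kcal/mol
#' @slot occupancies observed per-well sample fractions
#' @slot transitions inter-well transition count in the base series
#' @slot ergodic logical ergodicity flag
#' @export
setClass("TorsionProfileReport",
  representation(profile = "data.frame", histogram = "data.frame",
                 minima = "numeric", barriers = "numeric",
                 occupancies = "numeric", transitions = "numeric",
                 ergodic = "logical"),
  validity = function(object) {
    if (any(object@barriers < 0)) return("barriers must be >= 0")
    TRUE
  })

## ---------------------------------------------------------------------------
## Conformer ensembles and population fitting

#' Conformer ensemble
#'
#' A set of conformers sharing a torsion schema, with optional energies,
#' labeled 3D coordinates and per-conformer predicted NMR observables.
#'
#' @slot ids unique conformer labels
#' @slot torsions conformers x bonds matrix of torsions, degrees in
#'   [-180, 180)
#' @slot energies relative energies, kcal/mol (NA when unknown)
#' @slot coords list (one per conformer) of atoms x 3 coordinate matrices
#'   with consistent rownames (atom labels), or empty list
#' @slot predicted conformers x observables matrix of predicted values;
#'   column names identify the observables
#' @slot obsKind observable kind per predicted column: "shift", "coupling"
#'   or "distance"
#' @slot alignmentRef optional substructure specifier (e.g. SMARTS) used for
#'   alignment bookkeeping; purely annotation here
#' @export
setClass("ConformerEnsemble",
  representation(ids = "character", torsions = "matrix", energies = "numeric",
                 coords = "list", predicted = "matrix", obsKind = "character",
                 alignmentRef = "character"),
  validity = function(object) {
    msg <- character()
    n <- length(object@ids)
    if (anyDuplicated(object@ids)) msg <- c(msg, "conformer ids must be unique")
    if (nrow(object@torsions) != n)
      msg <- c(msg, "one torsion row per conformer is required")
    if (nrow(object@torsions) > 0 &&
        any(object@torsions < -180 | object@torsions >= 180))
      msg <- c(msg, "torsions must be wrapped to [-180, 180)")
    if (length(object@energies) != n)
      msg <- c(msg, "one energy per conformer is required (NA allowed)")
    if (length(object@coords) > 0) {
      if (length(object@coords) != n)
        msg <- c(msg, "coords must be empty or one matrix per conformer")
      labs <- lapply(object@coords, rownames)
      if (length(unique(labs)) > 1)
        msg <- c(msg, "atom labels must be consistent across the ensemble")
    }
    if (length(object@predicted) > 0) {
      if (nrow(object@predicted) != n)
        msg <- c(msg, "one predicted row per conformer is required")
      if (length(object@obsKind) != ncol(object@predicted))
        msg <- c(msg, "obsKind must label every predicted column")
      if (length(object@obsKind) &&
          !all(object@obsKind %in% c("shift", "coupling", "distance")))
        msg <- c(msg, "obsKind must be shift, coupling or distance")
    }
    if (length(msg)) msg else TRUE
  })

#' @rdname ConformerEnsemble-class
#' @param torsions conformers x bonds matrix (degrees; wrapped on input)
#' @param ids conformer labels (default conf1, conf2, ...)
#' @param energies optional energies, kcal/mol
#' @param coords optional list of labeled coordinate matrices
#' @param predicted optional conformers x observables prediction matrix
#' @param obsKind kinds of the predicted columns
#' @param alignmentRef optional substructure specifier
#' @export
ConformerEnsemble <- function(torsions, ids = NULL, energies = NULL,
                              coords = list(), predicted = NULL,
                              obsKind = character(), alignmentRef = "") {
  torsions <- as.matrix(torsions)
  storage.mode(torsions) <- "double"
  torsions[] <- .wrapDeg(torsions)
  n <- nrow(torsions)
  if (is.null(ids)) ids <- paste0("conf", seq_len(n))
  if (is.null(energies)) energies <- rep(NA_real_, n)
  if (is.null(predicted)) predicted <- matrix(numeric(0), nrow = n, ncol = 0)
  new("ConformerEnsemble", ids = as.character(ids), torsions = torsions,
      energies = as.numeric(energies), coords = coords,
      predicted = as.matrix(predicted), obsKind = as.character(obsKind),
      alignmentRef = alignmentRef)
}

#' Number of conformers
#' @param ensemble a \linkS4class{ConformerEnsemble}
#' @export
nConformers <- function(ensemble) length(ensemble@ids)

#' Conformer ids
#' @param ensemble a \linkS4class{ConformerEnsemble}
#' @export
conformerIds <- function(ensemble) ensemble@ids

#' Predicted observable matrix
#' @param ensemble a \linkS4class{ConformerEnsemble}
#' @export
predictedObservables <- function(ensemble) ensemble@predicted

#' Experimental observables for population fitting
#'
#' @slot observables data.frame with columns \code{name}, \code{kind}
#'   ("shift", "coupling" or "distance"), \code{value}, \code{unit},
#'   \code{weight} (> 0)
#' @export
setClass("ObservedData",
  representation(observables = "data.frame"),
  validity = function(object) {
    d <- object@observables
    need <- c("name", "kind", "value", "unit", "weight")
    if (!all(need %in% names(d)))
      return(paste("observables must have columns",
                   paste(need, collapse = ", ")))
    msg <- character()
    if (any(d$weight <= 0)) msg <- c(msg, "weights must be > 0")
    if (!all(d$kind %in% c("shift", "coupling", "distance")))
      msg <- c(msg, "kind must be shift, coupling or distance")
    if (anyDuplicated(d$name)) msg <- c(msg, "observable names must be unique")
    kindUnit <- unique(d[, c("kind", "unit")])
    if (anyDuplicated(kindUnit$kind))
      msg <- c(msg, "units must be consistent within an observable kind")
    if (length(msg)) msg else TRUE
  })

#' @rdname ObservedData-class
#' @param name,kind,value,weight parallel vectors describing the observables
#' @param unit units; defaults to ppm / Hz / Angstrom by kind
#' @export
ObservedData <- function(name, kind, value, weight = 1, unit = NULL) {
  if (is.null(unit))
    unit <- c(shift = "ppm", coupling = "Hz", distance = "Angstrom")[kind]
  new("ObservedData", observables = data.frame(
    name = as.character(name), kind = as.character(kind),
    value = as.numeric(value), unit = as.character(unit),
    weight = rep_len(as.numeric(weight), length(name)),
    stringsAsFactors = FALSE))
}

#' Simplex-constrained conformer population fit
#'
#' @slot weights fitted populations, named by conformer id; non-negative,
#'   sum to 1 (pruned conformers carry weight 0)
#' @slot ssd weighted sum of squared differences at the solution
#' @slot residuals data.frame(name, kind, observed, calculated, residual,
#'   weight)
#' @slot pruned ids of conformers removed below the pruning threshold
#' @export
setClass("PopulationFit",
  representation(weights = "numeric", ssd = "numeric",
                 residuals = "data.frame", pruned = "character"),
  validity = function(object) {
    msg <- character()
    if (any(object@weights < -1e-12)) msg <- c(msg, "weights must be >= 0")
    if (abs(sum(object@weights) - 1) > 1e-9)
      msg <- c(msg, "weights must sum to 1 (within 1e-9)")
    if (object@ssd < 0) msg <- c(msg, "ssd must be >= 0")
    if (length(msg)) msg else TRUE
  })

## ---------------------------------------------------------------------------
## Shift lists

#' Parsed proton shift list
#'
#' @slot compound compound identifier (free text)
#' @slot frequencyMHz spectrometer frequency, MHz
#' @slot solvent solvent label as printed
#' @slot entries data.frame, one row per parenthesized group as printed
#'   (descending delta): \code{delta} (midpoint, ppm), \code{deltaLow},
#'   \code{deltaHigh}, \code{multiplicity}, \code{jValues} (list column, Hz),
#'   \code{integral} (proton count; exact halves preserved),
#'   \code{isomerTag} ("isomer1", "isomer2", "both" or NA), \code{raw}
#'   (verbatim text of the group)
#' @slot problems character vector of spans that failed to parse
#' @export
setClass("ShiftList",
  representation(compound = "character", frequencyMHz = "numeric",
                 solvent = "character", entries = "data.frame",
                 problems = "character"),
  validity = function(object) {
    d <- object@entries
    msg <- character()
    if (nrow(d)) {
      if (any(d$integral <= 0)) msg <- c(msg, "integrals must be > 0")
      if (any(d$deltaLow > d$deltaHigh))
        msg <- c(msg, "delta ranges must have low <= high")
      jneg <- vapply(d$jValues, function(j) any(j < 0), logical(1))
      if (any(jneg)) msg <- c(msg, "J values must be >= 0")
    }
    if (length(msg)) msg else TRUE
  })
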