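## Synthetic-data generators: every input the pipeline consumes can be
## produced here with known ground truth (recorded in a provenance block),
## standing in for the spectrometer and for MD/QM predictions. All
## generators are pure functions of their configuration and seed.

#' Generate a variable-temperature EXSY build-up dataset
#'
#' Rates follow the Arrhenius law of \code{truth} at its temperatures;
#' intensities follow the equal-population two-site build-up model
#' (\code{\link{buildupModel}}), optionally damped by T1, plus additive
#' Gaussian noise on the normalized intensity scale. The ground-truth rates
#' and all generator parameters are recorded in the provenance block.
#'
#' @param truth an \linkS4class{ArrheniusTruth}
#' @param mixingTimes mixing times, s (> 0); default the standard
#'   eight-point schedule 0.1-2 s
#' @param sigma standard deviation of the additive intensity noise
#'   (dimensionless; >= 0)
#' @param seed RNG seed
#' @param t1 optional longitudinal relaxation time, s
#' @return an \linkS4class{EXSYDataset} with provenance
#' @examples
#' truth <- arrheniusTruth(ea = 19.9, kRef = 1.386, tRef = 300)
#' ds <- genExsyDataset(truth, sigma = 0, seed = 1)
#' exsyTemperatures(ds)
#' @export
genExsyDataset <- function(truth,
                           mixingTimes = c(0.1, 0.2, 0.3, 0.4, 0.5, 0.7,
                                           1, 2),
                           sigma = 0.02, seed = 1, t1 = NULL) {
  stopifnot(is(truth, "ArrheniusTruth"))
  if (length(mixingTimes) == 0 || any(mixingTimes <= 0))
    stop("mixing times must be non-empty and > 0")
  if (sigma < 0) stop("sigma must be >= 0")
  mixingTimes <- sort(mixingTimes)
  temps <- truth@temperatures
  k <- arrheniusRate(truth, temps)
  set.seed(seed)
  rows <- lapply(seq_along(temps), function(i) {
    f <- buildupModel(k[i], mixingTimes, t1)
    data.frame(temperature_K = temps[i], mixing_time_s = mixingTimes,
               intensity = f + stats::rnorm(length(f), 0, sigma))
  })
  EXSYDataset(do.call(rbind, rows), provenance = list(
    ea = truth@ea, lnA = truth@lnA,
    k = stats::setNames(k, as.character(temps)),
    sigma = sigma, seed = seed, t1 = t1,
    model = "equal-population two-site build-up",
    noise = "additive Gaussian on normalized intensity"))
}

#' Generate a variable-temperature lineshape stack
#'
#' One simulated spectrum per temperature, with the exchange rate constant
#' taken from the Arrhenius law (\code{kEx = k(T) / pB}, i.e. 2 k(T) for a
#' 1:1 pair): the stack walks from slow exchange (two resolved lines)
#' through coalescence to fast exchange (one narrowing line) as the rate
#' passes the coalescence threshold.
#'
#' @param system an \linkS4class{ExchangeSystem}; its \code{kEx} slot is
#'   overridden per temperature
#' @param temperatures stack temperatures, K
#' @param truth an \linkS4class{ArrheniusTruth} supplying k(T)
#' @param grid frequency axis, Hz (must span both sites)
#' @return list of \linkS4class{Spectrum}, named by temperature, with a
#'   \code{provenance} attribute recording k(T) and kEx(T)
#' @export
genVTSpectrumStack <- function(system, temperatures, truth, grid) {
  stopifnot(is(system, "ExchangeSystem"), is(truth, "ArrheniusTruth"))
  k <- arrheniusRate(truth, temperatures)
  kEx <- k / system@pB
  out <- lapply(seq_along(temperatures), function(i) {
    sys <- initialize(system, kEx = kEx[i])
    simulateLineshape(sys, grid)
  })
  names(out) <- as.character(temperatures)
  attr(out, "provenance") <- list(
    temperatures = temperatures,
    k = stats::setNames(k, as.character(temperatures)),
    kEx = stats::setNames(kEx, as.character(temperatures)),
    ea = truth@ea, lnA = truth@lnA)
  out
}

#' Default synthetic shift predictor
#'
#' Builds a smooth periodic map from torsions to predicted chemical shifts:
#' each observable is a fixed random cosine/sine combination of the bond
#' torsions around a baseline in the 1-9 ppm range. The map is a pure
#' function of \code{seed}, standing in for a quantum-chemical shift
#' predictor.
#'
#' @param nObs number of predicted observables
#' @param nBonds number of torsion coordinates the map consumes
#' @param seed RNG seed fixing the map
#' @param amplitude ppm scale of the torsional modulation
#' @return function(torsions matrix) -> conformers x nObs matrix with
#'   column names H1, H2, ...
#' @export
makeShiftObservableModel <- function(nObs = 8, nBonds = 3, seed = 1,
                                     amplitude = 0.8) {
  set.seed(seed)
  base <- stats::runif(nObs, 1, 9)
  A <- matrix(stats::rnorm(nObs * nBonds, 0, amplitude), nObs, nBonds)
  B <- matrix(stats::rnorm(nObs * nBonds, 0, amplitude), nObs, nBonds)
  function(torsions) {
    torsions <- as.matrix(torsions)
    stopifnot(ncol(torsions) == nBonds)
    rad <- torsions * pi / 180
    pred <- cos(rad) %*% t(A) + sin(rad) %*% t(B)
    pred <- sweep(pred, 2, base, `+`)
    colnames(pred) <- paste0("H", seq_len(nObs))
    pred
  }
}

#' Generate a conformer ensemble with known population weights
#'
#' Draws conformer torsions, predicts per-conformer observables through a
#' (fixed, seeded) observable model, and produces the observed data as the
#' population-weighted ensemble average at the true weights plus additive
#' Gaussian noise. The true weights (padded with zeros over any decoy
#' conformers) are recorded in the provenance block, enabling recovery
#' tests without re-deriving them.
#'
#' @param trueWeights simplex weights of the first
#'   \code{length(trueWeights)} conformers (>= 0, sum 1 within 1e-9)
#' @param nConformers total conformers (>= length(trueWeights); extras are
#'   zero-weight decoys)
#' @param observableModel function(torsions) -> prediction matrix; default
#'   \code{\link{makeShiftObservableModel}} with \code{nBonds} bonds
#' @param sigma additive Gaussian noise on the observed values (ppm)
#' @param seed RNG seed
#' @param nBonds torsion coordinates per conformer
#' @return list with \code{ensemble} (\linkS4class{ConformerEnsemble}),
#'   \code{observed} (\linkS4class{ObservedData}) and \code{provenance}
#' @examples
#' syn <- genConformerEnsemble(c(0.7, 0.3), nConformers = 2, sigma = 0)
#' fitWeights(fitPopulations(syn$ensemble, syn$observed))
#' @export
genConformerEnsemble <- function(trueWeights, nConformers =
                                   length(trueWeights),
                                 observableModel = NULL, sigma = 0,
                                 seed = 1, nBonds = 3) {
  if (any(trueWeights < 0) || abs(sum(trueWeights) - 1) > 1e-9)
    stop("trueWeights must be non-negative and sum to 1 (within 1e-9)")
  if (nConformers < length(trueWeights))
    stop("nConformers must be >= length(trueWeights)")
  if (sigma < 0) stop("sigma must be >= 0")
  if (is.null(observableModel))
    observableModel <- makeShiftObservableModel(nBonds = nBonds, seed = seed)
  set.seed(seed + 1)
  torsions <- matrix(stats::runif(nConformers * nBonds, -180, 180),
                     nConformers, nBonds)
  pred <- observableModel(torsions)
  ens <- ConformerEnsemble(torsions = torsions, predicted = pred,
                           obsKind = rep("shift", ncol(pred)))
  w <- c(trueWeights, rep(0, nConformers - length(trueWeights)))
  avg <- ensembleAverageObservables(ens, w)
  obs <- ObservedData(name = names(avg), kind = rep("shift", length(avg)),
                      value = avg + stats::rnorm(length(avg), 0, sigma))
  list(ensemble = ens, observed = obs,
       provenance = list(trueWeights = w, sigma = sigma, seed = seed))
}

#' Generate a multi-well torsional conformer ensemble
#'
#' Conformers drawn from a mixture of Gaussian wells independently per
#' bond, the shape of an extensively sampled torsional ensemble; used as
#' the package-scale clustering fixture (3 bonds x 3 wells gives 27
#' natural clusters).
#'
#' @param n conformer count (default 1002, a routine sampling size)
#' @param wells well centers, degrees
#' @param sdDeg within-well spread, degrees
#' @param nBonds number of rotatable bonds
#' @param seed RNG seed
#' @return a \linkS4class{ConformerEnsemble} with a \code{wellIndex}
#'   attribute (n x nBonds matrix of generating wells)
#' @export
genWellEnsemble <- function(n = 1002, wells = c(-60, 60, 180), sdDeg = 8,
                            nBonds = 3, seed = 1) {
  set.seed(seed)
  idx <- matrix(sample.int(length(wells), n * nBonds, replace = TRUE),
                n, nBonds)
  tor <- matrix(wells[idx] + stats::rnorm(n * nBonds, 0, sdDeg), n, nBonds)
  ens <- ConformerEnsemble(torsions = .wrapDeg(tor))
  attr(ens, "wellIndex") <- idx
  ens
}

## ---------------------------------------------------------------------------
## JSON serialization with provenance

#' Write / read an EXSY dataset as JSON
#'
#' JSON object with a \code{provenance} block and a \code{data} record of
#' arrays, the interchange format of the pipeline stages.
#'
#' @param dataset an \linkS4class{EXSYDataset}
#' @param path file path
#' @return \code{writeEXSYJson}: the path, invisibly; \code{readEXSYJson}:
#'   an \linkS4class{EXSYDataset}
#' @export
writeEXSYJson <- function(dataset, path) {
  stopifnot(is(dataset, "EXSYDataset"))
  jsonlite::write_json(list(provenance = dataset@provenance,
                            data = dataset@data),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname writeEXSYJson
#' @export
readEXSYJson <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  prov <- if (is.null(x$provenance)) list() else as.list(x$provenance)
  EXSYDataset(as.data.frame(x$data), provenance = prov)
}

#' Write / read a conformer ensemble as JSON
#'
#' @param ensemble a \linkS4class{ConformerEnsemble}
#' @param path file path
#' @return \code{writeEnsembleJson}: the path, invisibly;
#'   \code{readEnsembleJson}: a \linkS4class{ConformerEnsemble}
#' @export
writeEnsembleJson <- function(ensemble, path) {
  stopifnot(is(ensemble, "ConformerEnsemble"))
  x <- list(ids = ensemble@ids,
            torsions = ensemble@torsions,
            energies = ensemble@energies,
            obsKind = ensemble@obsKind,
            alignmentRef = ensemble@alignmentRef)
  if (ncol(ensemble@predicted)) {
    x$predicted <- ensemble@predicted
    x$observableNames <- colnames(ensemble@predicted)
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname writeEnsembleJson
#' @export
readEnsembleJson <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  pred <- NULL
  if (!is.null(x$predicted)) {
    pred <- as.matrix(x$predicted)
    colnames(pred) <- x$observableNames
  }
  ConformerEnsemble(torsions = as.matrix(x$torsions), ids = x$ids,
                    energies = x$energies, predicted = pred,
                    obsKind = if (is.null(x$obsKind)) character()
                              else x$obsKind,
                    alignmentRef = if (is.null(x$alignmentRef)) ""
                                   else x$alignmentRef)
}
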