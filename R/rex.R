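## Replica-exchange Metropolis sampling of torsional potentials: the
## desk-scale stand-in for solute-tempering MD. A single torsion is sampled
## on an analytic cosine-series potential by Metropolis updates at each
## ladder temperature, with neighbor swaps at a fixed interval; barrier
## crossing is delivered by the hot end of the ladder, exactly the
## phenomenology the method exists to probe.

#' Torsional potential from preset or cosine terms
#'
#' Presets encode the torsion phenotypes used throughout the package, with
#' barrier heights measured min-to-lowest-saddle:
#' \describe{
#'   \item{hindered_biaryl}{symmetric double well with minima near +/-90
#'     degrees and two unequal saddles; the lower barrier (at 180 degrees)
#'     is exactly 20 kcal/mol, the upper 22. Models a rigid biaryl-type
#'     bond showing rotamer doubling at room temperature.}
#'   \item{desmethyl}{the same topology scaled soft: lower barrier about
#'     5 kcal/mol (< 6), giving ready interconversion and averaged lines.}
#'   \item{flexible_threefold}{pure threefold term, three equal minima,
#'     3 kcal/mol barriers; a freely rotating sp3-type bond.}
#' }
#'
#' @param profile preset name, or a data.frame of cosine terms with columns
#'   \code{n}, \code{Vn} (kcal/mol), \code{gamma} (degrees)
#' @return a \linkS4class{TorsionPotential}
#' @examples
#' pot <- genTorsionPotential("hindered_biaryl")
#' barrierReport(pot)$headline
#' @export
genTorsionPotential <- function(profile) {
  if (is.character(profile)) {
    ## hindered_biaryl amplitude: lower barrier of a(1+cos 2phi)+(1+cos phi)
    ## is 2a - 1 + 1/(8a); a solves 16a^2 - 168a + 1 = 0 so it equals 20
    a <- (168 + sqrt(28160)) / 32
    terms <- switch(profile,
      hindered_biaryl = data.frame(n = c(2, 1), Vn = c(2 * a, 2),
                                   gamma = c(0, 0)),
      desmethyl = data.frame(n = c(2, 1), Vn = c(5.5, 1), gamma = c(0, 0)),
      flexible_threefold = data.frame(n = 3, Vn = 3, gamma = 0),
      stop("unknown preset '", profile, "'"))
    return(new("TorsionPotential", terms = terms, preset = profile))
  }
  new("TorsionPotential", terms = as.data.frame(profile), preset = "")
}

#' Evaluate a torsional potential
#'
#' @param potential a \linkS4class{TorsionPotential}
#' @param phi angle(s), degrees
#' @return energy, kcal/mol
#' @export
potentialEnergy <- function(potential, phi) {
  stopifnot(is(potential, "TorsionPotential"))
  t <- potential@terms
  torsion_potential_cpp(as.numeric(phi), t$n, t$Vn, t$gamma)
}

#' Build a geometric replica ladder
#'
#' Temperatures \code{T_i = tMin * (tMax/tMin)^(i/(m-1))}, i = 0..m-1, so
#' the ratio between consecutive replicas is constant and the endpoints are
#' exact. \code{m = 1} returns the single base temperature.
#'
#' @param tMin base temperature, K
#' @param tMax top temperature, K (>= tMin)
#' @param m replica count (>= 1)
#' @return ascending numeric vector of temperatures
#' @examples
#' buildLadder(300, 1263, 12)
#' buildLadder(300, 3302, 20)
#' @export
buildLadder <- function(tMin, tMax, m) {
  if (m < 1 || m != round(m)) stop("replica count m must be a positive integer")
  if (!(tMax >= tMin && tMin > 0)) stop("require tMax >= tMin > 0")
  if (m == 1) return(tMin)
  tMin * (tMax / tMin) ^ ((seq_len(m) - 1) / (m - 1))
}

#' Parallel-tempering swap probability and acceptance
#'
#' Standard criterion for swapping the configurations at neighboring
#' temperatures: accept with probability
#' \code{min(1, exp((1/(R*tI) - 1/(R*tJ)) * (eI - eJ)))}.
#'
#' @param eI,eJ configuration energies at temperatures tI, tJ, kcal/mol
#' @param tI,tJ replica temperatures, K (> 0)
#' @param rngDraw uniform(0,1) draw deciding acceptance
#' @return \code{exchangeAccept}: logical; \code{exchangeProbability}: the
#'   acceptance probability
#' @export
exchangeAccept <- function(eI, eJ, tI, tJ, rngDraw) {
  rngDraw < exchangeProbability(eI, eJ, tI, tJ)
}

#' @rdname exchangeAccept
#' @export
exchangeProbability <- function(eI, eJ, tI, tJ) {
  if (any(c(tI, tJ) <= 0)) stop("temperatures must be > 0")
  pmin(1, exp((1 / (GAS_CONSTANT_KCAL * tI) - 1 / (GAS_CONSTANT_KCAL * tJ)) *
                (eI - eJ)))
}

#' Run replica-exchange Metropolis sampling
#'
#' Each replica performs one Metropolis update per sweep (uniform angular
#' proposal of half-width \code{stepDeg}, wrapped periodically) at its own
#' ladder temperature; every \code{exchangeInterval} sweeps all neighboring
#' pairs attempt a configuration swap. A fixed seed makes the trajectory
#' bit-identical across runs.
#'
#' @param potential a \linkS4class{TorsionPotential}
#' @param ladder temperatures from \code{\link{buildLadder}} (ascending,
#'   first = base)
#' @param sweeps number of sweeps (>= 1)
#' @param startAngle initial torsion of every replica, degrees
#' @param stepDeg proposal half-width, degrees (> 0)
#' @param exchangeInterval sweeps between swap rounds
#' @param seed RNG seed
#' @return a \linkS4class{TorsionTrajectory}
#' @examples
#' pot <- genTorsionPotential("flexible_threefold")
#' traj <- runRex(pot, buildLadder(300, 300, 1), sweeps = 2000,
#'                startAngle = 60, seed = 1)
#' head(baseSeries(traj))
#' @export
runRex <- function(potential, ladder, sweeps, startAngle = 90,
                   stepDeg = 30, exchangeInterval = 10, seed = 1) {
  stopifnot(is(potential, "TorsionPotential"))
  if (sweeps < 1) stop("sweeps must be >= 1")
  if (stepDeg <= 0) stop("stepDeg must be > 0")
  if (any(diff(ladder) <= 0) && length(ladder) > 1)
    stop("ladder temperatures must be strictly increasing")
  t <- potential@terms
  set.seed(seed)
  res <- rex_sample_cpp(t$n, t$Vn, t$gamma, as.numeric(ladder),
                        as.integer(sweeps), startAngle, stepDeg,
                        as.integer(exchangeInterval))
  new("TorsionTrajectory", angles = res$angles, walkers = res$walkers,
      ladder = as.numeric(ladder),
      exchangeLog = data.frame(sweep = res$exchange_sweep,
                               pair = res$exchange_pair,
                               accepted = as.logical(res$exchange_accepted)),
      seed = seed, startAngle = startAngle, stepDeg = stepDeg,
      exchangeInterval = exchangeInterval)
}

#' Base-temperature angle series
#'
#' @param traj a \linkS4class{TorsionTrajectory}
#' @param burnIn fraction of initial sweeps to discard (0 <= burnIn < 1)
#' @return numeric vector of angles, degrees
#' @export
baseSeries <- function(traj, burnIn = 0) {
  stopifnot(is(traj, "TorsionTrajectory"))
  if (burnIn < 0 || burnIn >= 1) stop("burnIn must lie in [0, 1)")
  x <- traj@angles[, 1]
  drop <- floor(burnIn * length(x))
  if (drop >= length(x)) stop("no sweeps retained after burn-in")
  x[(drop + 1):length(x)]
}

#' Histogram of base-temperature torsions
#'
#' Counts over equal bins spanning [-180, 180) after burn-in discard,
#' optionally subsampled (evenly spaced frames) to a fixed ensemble size.
#' Counts sum to the number of retained samples.
#'
#' @param traj a \linkS4class{TorsionTrajectory}
#' @param bins number of bins (>= 2)
#' @param burnIn fraction of initial sweeps to discard
#' @param nFrames optional evenly spaced subsample size (e.g. 1002)
#' @return data.frame(mid, count) with attributes \code{breaks} and
#'   \code{retained}
#' @export
torsionHistogram <- function(traj, bins = 72, burnIn = 0.1, nFrames = NULL) {
  if (bins < 2) stop("bins must be >= 2")
  x <- baseSeries(traj, burnIn)
  if (!is.null(nFrames)) {
    if (nFrames < 1 || nFrames > length(x))
      stop("nFrames must lie in [1, retained samples]")
    x <- x[round(seq(1, length(x), length.out = nFrames))]
  }
  breaks <- seq(-180, 180, length.out = bins + 1)
  idx <- findInterval(x, breaks, rightmost.closed = FALSE)
  idx[idx > bins] <- bins  # guards x == 180 - eps rounding
  counts <- tabulate(idx, nbins = bins)
  out <- data.frame(mid = (breaks[-1] + breaks[-(bins + 1)]) / 2,
                    count = counts)
  attr(out, "breaks") <- breaks
  attr(out, "retained") <- length(x)
  out
}

#' Free-energy profile from a histogram
#'
#' Boltzmann inversion \code{dG(bin) = -R*T*log(count/max(count))}; empty
#' bins are masked as NA rather than returned as infinities.
#'
#' @param histogram data.frame(mid, count) from
#'   \code{\link{torsionHistogram}}
#' @param temperature temperature of the sampled series, K
#' @return data.frame(angle, dG) with NA for empty bins
#' @export
freeEnergyProfile <- function(histogram, temperature) {
  counts <- histogram$count
  if (all(counts == 0)) stop("all-zero histogram")
  dG <- -GAS_CONSTANT_KCAL * temperature * log(counts / max(counts))
  dG[counts == 0] <- NA_real_
  data.frame(angle = histogram$mid, dG = dG)
}

#' Locate minima, saddles and barriers of a torsional potential
#'
#' Dense periodic grid scan followed by local golden-section refinement.
#' For each well the barrier is the height from its minimum to each
#' adjacent saddle (per-direction); the per-well barrier is the lower of
#' the two, and the headline barrier is the lower adjacent-saddle height
#' above the global-minimum well.
#'
#' @param potential a \linkS4class{TorsionPotential}
#' @param gridStep scan resolution, degrees
#' @return list with \code{wells} (data.frame: minimum, vMin, leftSaddle,
#'   rightSaddle, barrierLeft, barrierRight, barrier), \code{saddles}
#'   (data.frame: angle, v), \code{headline} (kcal/mol) and
#'   \code{degenerate} (flat-potential flag)
#' @export
barrierReport <- function(potential, gridStep = 0.05) {
  stopifnot(is(potential, "TorsionPotential"))
  phi <- seq(-180, 180 - gridStep, by = gridStep)
  v <- potentialEnergy(potential, phi)
  n <- length(phi)
  if (diff(range(v)) < 1e-9) {
    return(list(wells = data.frame(minimum = numeric(0), vMin = numeric(0),
                                   leftSaddle = numeric(0),
                                   rightSaddle = numeric(0),
                                   barrierLeft = numeric(0),
                                   barrierRight = numeric(0),
                                   barrier = numeric(0)),
                saddles = data.frame(angle = numeric(0), v = numeric(0)),
                headline = 0, degenerate = TRUE))
  }
  prv <- c(n, seq_len(n - 1))
  nxt <- c(seq_len(n - 1) + 1, 1)
  isMin <- v < v[prv] & v < v[nxt]
  isMax <- v > v[prv] & v > v[nxt]
  refine <- function(i, maximize) {
    ## refine within the bracketing grid interval, unwrapped locally
    lo <- phi[i] - gridStep
    hi <- phi[i] + gridStep
    f <- function(x) potentialEnergy(potential, .wrapDeg(x))
    opt <- stats::optimize(f, c(lo, hi), maximum = maximize, tol = 1e-10)
    if (maximize) c(angle = .wrapDeg(opt$maximum), v = opt$objective)
    else c(angle = .wrapDeg(opt$minimum), v = opt$objective)
  }
  minima <- t(vapply(which(isMin), refine, numeric(2), maximize = FALSE))
  saddles <- t(vapply(which(isMax), refine, numeric(2), maximize = TRUE))
  minima <- minima[order(minima[, "angle"]), , drop = FALSE]
  saddles <- saddles[order(saddles[, "angle"]), , drop = FALSE]
  nw <- nrow(minima)
  ## cyclic pairing: the saddle left of well w separates it from well w-1
  leftSad <- numeric(nw); rightSad <- numeric(nw)
  for (w in seq_len(nw)) {
    below <- saddles[saddles[, "angle"] < minima[w, "angle"], , drop = FALSE]
    above <- saddles[saddles[, "angle"] > minima[w, "angle"], , drop = FALSE]
    leftSad[w] <- if (nrow(below)) below[nrow(below), "v"]
                  else saddles[nrow(saddles), "v"]
    rightSad[w] <- if (nrow(above)) above[1, "v"] else saddles[1, "v"]
  }
  wells <- data.frame(minimum = minima[, "angle"], vMin = minima[, "v"],
                      leftSaddle = leftSad, rightSaddle = rightSad,
                      barrierLeft = leftSad - minima[, "v"],
                      barrierRight = rightSad - minima[, "v"])
  wells$barrier <- pmin(wells$barrierLeft, wells$barrierRight)
  g <- which.min(wells$vMin)
  list(wells = wells,
       saddles = data.frame(angle = saddles[, "angle"], v = saddles[, "v"]),
       headline = wells$barrier[g], degenerate = FALSE)
}

## internal: assign angles to wells, basin boundaries at saddle angles
.assignWells <- function(angles, report) {
  sadd <- sort(report$saddles$angle)
  mins <- report$wells$minimum
  if (length(sadd) == 0) return(rep(1L, length(angles)))
  ## interval index between consecutive saddles (cyclic)
  idx <- findInterval(angles, sadd)  # 0 .. length(sadd)
  idx[idx == 0] <- length(sadd)      # wrap: below first saddle = last arc
  ## map each cyclic arc to the well minimum it contains
  arcOfMin <- findInterval(mins, sadd)
  arcOfMin[arcOfMin == 0] <- length(sadd)
  well <- match(idx, arcOfMin)
  if (anyNA(well)) {
    ## an arc without a refined minimum (numerical corner); nearest minimum
    ## by periodic distance, ties toward the lower-index minimum
    nearest <- function(a) {
      d <- abs(.wrapDeg(a - mins))
      which.min(d)
    }
    bad <- which(is.na(well))
    well[bad] <- vapply(angles[bad], nearest, integer(1))
  }
  well
}

#' Ergodicity diagnostics of a sampled trajectory
#'
#' Assigns every retained base-temperature sample to a potential well
#' (basin boundaries at the saddle angles), counts inter-well transitions,
#' and flags the run ergodic when every thermally relevant well (Boltzmann
#' population above \code{popThreshold} at the base temperature) was
#' visited and the transition count reaches \code{minTransitions}.
#'
#' @param traj a \linkS4class{TorsionTrajectory}
#' @param potential the sampled \linkS4class{TorsionPotential}
#' @param burnIn fraction of initial sweeps to discard
#' @param popThreshold Boltzmann-population relevance threshold
#' @param minTransitions minimum inter-well transition count
#' @return list with \code{occupancies}, \code{boltzmann} (both per well),
#'   \code{transitions}, \code{ergodic}, \code{wells} (the barrier report)
#' @export
ergodicityDiagnostics <- function(traj, potential, burnIn = 0.1,
                                  popThreshold = 0.05, minTransitions = 10) {
  x <- baseSeries(traj, burnIn)
  report <- barrierReport(potential)
  if (report$degenerate)
    return(list(occupancies = 1, boltzmann = 1, transitions = 0,
                ergodic = TRUE, wells = report))
  nw <- nrow(report$wells)
  well <- .assignWells(x, report)
  occ <- tabulate(well, nbins = nw) / length(well)
  ## Boltzmann weights of the basins at the base temperature
  grid <- seq(-180, 180 - 0.1, by = 0.1)
  vg <- potentialEnergy(potential, grid)
  wg <- exp(-(vg - min(vg)) / (GAS_CONSTANT_KCAL * traj@ladder[1]))
  basin <- .assignWells(grid, report)
  boltz <- vapply(seq_len(nw), function(w) sum(wg[basin == w]), numeric(1))
  boltz <- boltz / sum(boltz)
  transitions <- sum(diff(well) != 0)
  relevant <- boltz > popThreshold
  ergodic <- all(occ[relevant] > 0) && transitions >= minTransitions
  list(occupancies = occ, boltzmann = boltz, transitions = transitions,
       ergodic = ergodic, wells = report)
}

#' Radial time representation of a trajectory
#'
#' Maps sweep index linearly to radius and the base-temperature angle to
#' azimuth, the spiral-outward display of sampling progress; the first and
#' last retained points are flagged.
#'
#' @param traj a \linkS4class{TorsionTrajectory}
#' @param burnIn fraction of initial sweeps to discard
#' @return data.frame(sweep, radius, angle, endpoint)
#' @export
radialSeries <- function(traj, burnIn = 0) {
  x <- baseSeries(traj, burnIn)
  n <- length(x)
  sweep0 <- nrow(traj@angles) - n
  data.frame(sweep = sweep0 + seq_len(n) - 1,
             radius = if (n == 1) 1 else (seq_len(n) - 1) / (n - 1),
             angle = x,
             endpoint = seq_len(n) %in% c(1L, n))
}

#' Full torsion profile report
#'
#' Bundles the analytic profile, base-temperature histogram, well and
#' barrier analysis and the ergodicity verdict for one sampled torsion.
#'
#' @param traj a \linkS4class{TorsionTrajectory}
#' @param potential the sampled \linkS4class{TorsionPotential}
#' @param bins histogram bins
#' @param burnIn burn-in fraction
#' @param nFrames optional subsample size for the histogram
#' @return a \linkS4class{TorsionProfileReport}
#' @export
rexReport <- function(traj, potential, bins = 72, burnIn = 0.1,
                      nFrames = NULL) {
  h <- torsionHistogram(traj, bins = bins, burnIn = burnIn, nFrames = nFrames)
  diag <- ergodicityDiagnostics(traj, potential, burnIn = burnIn)
  grid <- seq(-180, 179.5, by = 0.5)
  new("TorsionProfileReport",
      profile = data.frame(angle = grid, V = potentialEnergy(potential, grid)),
      histogram = h,
      minima = diag$wells$wells$minimum,
      barriers = diag$wells$wells$barrier,
      occupancies = diag$occupancies,
      transitions = diag$transitions,
      ergodic = diag$ergodic)
}
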