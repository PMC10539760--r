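## Conformer ensemble tools: periodic torsion metric, Kabsch superposition
## RMSD, complete-linkage clustering with nearest-to-centroid
## representatives and mirror-image discarding, Boltzmann populations and
## ensemble-averaged NMR observables.

#' Periodic torsion-space distance
#'
#' Root-mean-square of per-angle differences, each wrapped to
#' [-180, 180], so 179 and -179 degrees are 2 degrees apart.
#'
#' @param a,b torsion vectors, degrees, equal length
#' @return distance, degrees
#' @examples
#' torsionDistance(179, -179) # 2
#' @export
torsionDistance <- function(a, b) {
  if (length(a) != length(b)) stop("torsion vectors must have equal length")
  d <- .wrapDeg(a - b)
  sqrt(mean(d ^ 2))
}

#' Cartesian RMSD with optional Kabsch superposition
#'
#' Least-squares optimal-rotation superposition over matched atom labels.
#' Proper rotations only by default; with \code{allowMirror = TRUE} the
#' unconstrained orthogonal solution (possibly an improper rotation) is
#' used, which makes a structure and its mirror image superpose exactly.
#'
#' @param a,b atoms x 3 coordinate matrices, Angstrom, with identical
#'   rownames (atom labels)
#' @param superpose optimally superpose before measuring (default TRUE)
#' @param allowMirror permit improper rotations (reflections)
#' @return RMSD, Angstrom
#' @export
cartesianRmsd <- function(a, b, superpose = TRUE, allowMirror = FALSE) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!identical(dim(a), dim(b))) stop("coordinate sets differ in size")
  if (is.null(rownames(a)) || is.null(rownames(b)) ||
      !setequal(rownames(a), rownames(b)) || anyDuplicated(rownames(a)))
    stop("coordinates must carry matching unique atom labels")
  b <- b[rownames(a), , drop = FALSE]
  if (superpose) {
    ca <- sweep(a, 2, colMeans(a))
    cb <- sweep(b, 2, colMeans(b))
    s <- svd(crossprod(cb, ca))   # Kabsch: rotate b onto a
    d <- sign(det(s$u %*% t(s$v)))
    corr <- if (allowMirror) c(1, 1, 1) else c(1, 1, d)
    rot <- s$u %*% diag(corr) %*% t(s$v)
    bR <- cb %*% rot
    return(sqrt(mean(rowSums((ca - bR) ^ 2))))
  }
  sqrt(mean(rowSums((a - b) ^ 2)))
}

## internal: pairwise distance matrix under the chosen metric
.conformerDist <- function(ensemble, metric) {
  n <- nConformers(ensemble)
  if (metric == "cartesian-rmsd" && length(ensemble@coords) == 0)
    stop("cartesian-rmsd metric requires conformer coordinates")
  if (metric == "torsion") {
    ## vectorized: accumulate wrapped squared differences per bond
    tor <- ensemble@torsions
    acc <- matrix(0, n, n)
    for (b in seq_len(ncol(tor)))
      acc <- acc + .wrapDeg(outer(tor[, b], tor[, b], `-`)) ^ 2
    return(sqrt(acc / ncol(tor)))
  }
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(i - 1)) {
    d[i, j] <- d[j, i] <- cartesianRmsd(ensemble@coords[[i]],
                                        ensemble@coords[[j]])
  }
  d
}

## internal: distance of conformer i to the mirror image of conformer j
.mirrorDist <- function(ensemble, metric, i, j) {
  if (metric == "torsion") {
    torsionDistance(ensemble@torsions[i, ], .wrapDeg(-ensemble@torsions[j, ]))
  } else {
    m <- ensemble@coords[[j]]
    m[] <- -m  # point inversion; superposition absorbs the orientation
    cartesianRmsd(ensemble@coords[[i]], m)
  }
}

#' Cluster a conformer ensemble to diverse representatives
#'
#' Complete-linkage agglomerative clustering under the chosen metric, cut
#' at \code{threshold}; the representative of each cluster is the member
#' minimizing the summed distance to its cluster (nearest to centroid),
#' with deterministic ties broken by conformer order. With
#' \code{discardMirrors}, clusters (processed in order of their first
#' member) whose representative's mirror image lies within
#' \code{threshold} of an already retained representative are dropped,
#' the convention used when enantiomeric conformations are redundant.
#'
#' @param ensemble a \linkS4class{ConformerEnsemble}
#' @param metric "torsion" (periodic RMS over torsions, degrees) or
#'   "cartesian-rmsd" (Kabsch-superposed RMSD, Angstrom; requires coords)
#' @param threshold cluster cut height in metric units (default 30 degrees
#'   for the torsion metric)
#' @param discardMirrors drop mirror-redundant clusters
#' @return list with \code{representatives} (a
#'   \linkS4class{ConformerEnsemble}), \code{assignment} (cluster index per
#'   input conformer), \code{representativeIds} and \code{discarded}
#'   (ids of mirror-dropped representatives)
#' @export
clusterConformers <- function(ensemble, metric = c("torsion",
                                                   "cartesian-rmsd"),
                              threshold = 30, discardMirrors = FALSE) {
  metric <- match.arg(metric)
  stopifnot(is(ensemble, "ConformerEnsemble"))
  n <- nConformers(ensemble)
  if (n < 1) stop("at least one conformer is required")
  if (n == 1) {
    assignment <- 1L
    d <- matrix(0, 1, 1)
  } else {
    d <- .conformerDist(ensemble, metric)
    hc <- stats::hclust(stats::as.dist(d), method = "complete")
    assignment <- stats::cutree(hc, h = threshold)
    ## relabel clusters in order of first appearance for determinism
    assignment <- match(assignment, unique(assignment))
  }
  k <- max(assignment)
  reps <- integer(k)
  for (c in seq_len(k)) {
    members <- which(assignment == c)
    sums <- rowSums(d[members, members, drop = FALSE])
    reps[c] <- members[which.min(sums)]  # which.min ties -> lowest index
  }
  discarded <- character(0)
  keep <- rep(TRUE, k)
  if (discardMirrors && k > 1) {
    for (c in 2:k) {
      prior <- reps[which(keep[seq_len(c - 1)])]
      mirrorHit <- any(vapply(prior, function(p)
        .mirrorDist(ensemble, metric, p, reps[c]) <= threshold, logical(1)))
      if (mirrorHit) {
        keep[c] <- FALSE
        discarded <- c(discarded, ensemble@ids[reps[c]])
      }
    }
  }
  sel <- reps[keep]
  repEns <- ConformerEnsemble(
    torsions = ensemble@torsions[sel, , drop = FALSE],
    ids = ensemble@ids[sel],
    energies = ensemble@energies[sel],
    coords = if (length(ensemble@coords)) ensemble@coords[sel] else list(),
    predicted = if (ncol(ensemble@predicted))
      ensemble@predicted[sel, , drop = FALSE] else NULL,
    obsKind = ensemble@obsKind,
    alignmentRef = ensemble@alignmentRef)
  list(representatives = repEns, assignment = assignment,
       representativeIds = ensemble@ids[sel], discarded = discarded)
}

#' Boltzmann populations from conformer energies
#'
#' Weights proportional to \code{exp(-E/(R*T))}, normalized to the
#' simplex; invariant to adding any constant to all energies.
#'
#' @param energies conformer energies, kcal/mol (finite)
#' @param temperature temperature, K (> 0)
#' @return weights summing to 1
#' @examples
#' boltzmannPopulations(c(0, 0), 300)                 # 0.5, 0.5
#' boltzmannPopulations(c(0, 0.6549487), 300)         # 0.75, 0.25
#' @export
boltzmannPopulations <- function(energies, temperature) {
  if (length(energies) == 0) stop("empty energy list")
  if (any(!is.finite(energies))) stop("energies must be finite")
  if (temperature <= 0) stop("temperature must be > 0")
  w <- exp(-(energies - min(energies)) / (GAS_CONSTANT_KCAL * temperature))
  w / sum(w)
}

#' Population-weighted ensemble-average observables
#'
#' Chemical shifts and scalar couplings average linearly; interproton
#' distances average as \code{(sum w_i r_i^-6)^(-1/6)} by default (the NOE
#' intensity average), with \code{r^-3} exposed as an alternative.
#'
#' @param ensemble a \linkS4class{ConformerEnsemble} with predictions for
#'   every conformer
#' @param weights simplex weights matching the conformer count
#' @param distanceAveraging "r6" (default) or "r3"
#' @return named numeric vector of averaged observables (one per predicted
#'   column)
#' @examples
#' ens <- ConformerEnsemble(torsions = matrix(c(0, 120), ncol = 1),
#'                          predicted = matrix(c(2, 4), ncol = 1,
#'                            dimnames = list(NULL, "H1")),
#'                          obsKind = "shift")
#' ensembleAverageObservables(ens, c(0.5, 0.5)) # 3 ppm
#' @export
ensembleAverageObservables <- function(ensemble, weights,
                                       distanceAveraging = c("r6", "r3")) {
  distanceAveraging <- match.arg(distanceAveraging)
  stopifnot(is(ensemble, "ConformerEnsemble"))
  p <- ensemble@predicted
  if (ncol(p) == 0) stop("ensemble carries no predicted observables")
  if (anyNA(p)) stop("every conformer needs a prediction for every observable")
  if (length(weights) != nrow(p))
    stop("weights must match the conformer count")
  if (any(weights < -1e-12) || abs(sum(weights) - 1) > 1e-9)
    stop("weights must be non-negative and sum to 1")
  weights <- pmax(weights, 0)
  pw <- if (distanceAveraging == "r6") -6 else -3
  out <- numeric(ncol(p))
  for (j in seq_len(ncol(p))) {
    out[j] <- if (ensemble@obsKind[j] == "distance")
      sum(weights * p[, j] ^ pw) ^ (1 / pw)
    else sum(weights * p[, j])
  }
  names(out) <- colnames(p)
  out
}
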