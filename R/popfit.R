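## Simplex-constrained conformer population deconvolution: weighted least
## squares of population-averaged predicted observables against experiment.
## Shifts and couplings make the objective convex in the weights; r^-6
## distance averaging does not, hence the multi-start rule.

## internal: Euclidean projection onto the probability simplex (sort-based)
.projectSimplex <- function(v) {
  n <- length(v)
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u - (css - 1) / seq_len(n) > 0))
  theta <- (css[rho] - 1) / rho
  pmax(v - theta, 0)
}

## internal: build the weighted objective and gradient for a prediction
## matrix P (conformers x observables), observed values y, weights u
.makeObjective <- function(P, y, u, kinds, pw) {
  isDist <- kinds == "distance"
  Pd <- P
  Pd[, isDist] <- P[, isDist] ^ pw
  list(
    value = function(w) {
      calc <- as.numeric(crossprod(Pd, w))
      calc[isDist] <- calc[isDist] ^ (1 / pw)
      sum(u * (calc - y) ^ 2)
    },
    calc = function(w) {
      calc <- as.numeric(crossprod(Pd, w))
      calc[isDist] <- calc[isDist] ^ (1 / pw)
      calc
    },
    grad = function(w) {
      s <- as.numeric(crossprod(Pd, w))         # linear aggregate per obs
      calc <- s
      calc[isDist] <- s[isDist] ^ (1 / pw)
      r <- 2 * u * (calc - y)
      ## d calc / d w_i: linear cols -> Pd; distance cols -> chain rule
      jac <- Pd
      if (any(isDist)) {
        scale <- (1 / pw) * s[isDist] ^ (1 / pw - 1)
        jac[, isDist] <- sweep(Pd[, isDist, drop = FALSE], 2, scale, `*`)
      }
      as.numeric(jac %*% r)
    })
}

## internal: projected-gradient descent with backtracking from one start
.pgdSolve <- function(obj, w0, maxit = 20000, tol = 1e-14) {
  w <- .projectSimplex(w0)
  f <- obj$value(w)
  step <- 1
  for (it in seq_len(maxit)) {
    g <- obj$grad(w)
    ## backtracking on the projected step
    repeat {
      wNew <- .projectSimplex(w - step * g)
      fNew <- obj$value(wNew)
      if (fNew <= f - 1e-12 * sum((wNew - w) ^ 2) / max(step, 1e-300) ||
          step < 1e-18) break
      step <- step / 2
    }
    moved <- sqrt(sum((wNew - w) ^ 2))
    improved <- f - fNew
    w <- wNew
    f <- fNew
    step <- min(step * 2, 1e6)
    if (moved < 1e-12 && improved < tol) break
  }
  list(w = w, f = f)
}

#' Fit conformer populations against experimental observables
#'
#' Minimizes the weighted sum of squared differences between
#' population-averaged predicted observables
#' (\code{\link{ensembleAverageObservables}}) and the experimental values,
#' over the probability simplex. Deterministic multi-start projected
#' gradient: one start per simplex vertex plus the barycenter, best final
#' SSD wins, ties resolved to the lexicographically smallest weight
#' vector. After convergence, conformers with weight below
#' \code{pruneBelow} are removed and the fit re-run once on the survivors.
#'
#' @param ensemble a \linkS4class{ConformerEnsemble} whose \code{predicted}
#'   columns cover every observable in \code{observed} (matched by name)
#' @param observed an \linkS4class{ObservedData}
#' @param pruneBelow pruning threshold on fitted weights (default 0.01);
#'   0 disables pruning
#' @param kindWeights additional weight per observable kind applied on top
#'   of the per-observable weights (defaults: shift 1 per ppm^2, coupling
#'   0.1 per Hz^2, distance 1 per Angstrom^2)
#' @param distanceAveraging "r6" (default) or "r3"
#' @return a \linkS4class{PopulationFit}; weights are named by conformer id
#'   and pruned conformers carry weight 0
#' @examples
#' ens <- ConformerEnsemble(torsions = matrix(c(0, 120), ncol = 1),
#'                          predicted = matrix(c(2, 4, 1, 3), nrow = 2,
#'                            dimnames = list(NULL, c("H1", "H2"))),
#'                          obsKind = c("shift", "shift"))
#' obs <- ObservedData(c("H1", "H2"), c("shift", "shift"),
#'                     c(2.6, 1.6))  # generated at weights (0.7, 0.3)
#' fitWeights(fitPopulations(ens, obs))
#' @export
fitPopulations <- function(ensemble, observed, pruneBelow = 0.01,
                           kindWeights = c(shift = 1, coupling = 0.1,
                                           distance = 1),
                           distanceAveraging = c("r6", "r3")) {
  distanceAveraging <- match.arg(distanceAveraging)
  stopifnot(is(ensemble, "ConformerEnsemble"), is(observed, "ObservedData"))
  od <- observed@observables
  if (nrow(od) == 0) stop("observed data must be non-empty")
  n <- nConformers(ensemble)
  if (n < 1) stop("empty ensemble")
  pred <- ensemble@predicted
  missing <- setdiff(od$name, colnames(pred))
  if (length(missing))
    stop("no conformer predictions for observable(s): ",
         paste(missing, collapse = ", "))
  P <- pred[, od$name, drop = FALSE]
  if (anyNA(P)) stop("every conformer needs a prediction for every observable")
  u <- od$weight * unname(kindWeights[od$kind])
  pw <- if (distanceAveraging == "r6") -6 else -3
  obj <- .makeObjective(P, od$value, u, od$kind, pw)

  solveOn <- function(active) {
    na <- length(active)
    Psub <- P[active, , drop = FALSE]
    objA <- .makeObjective(Psub, od$value, u, od$kind, pw)
    starts <- c(lapply(seq_len(na), function(i) {
      w <- numeric(na); w[i] <- 1; w
    }), list(rep(1 / na, na)))
    sols <- lapply(starts, function(w0) .pgdSolve(objA, w0))
    fs <- vapply(sols, `[[`, numeric(1), "f")
    best <- min(fs)
    cand <- which(fs <= best + 1e-12 * (1 + best))
    ## tie rule: lexicographically smallest weight vector
    ws <- lapply(sols[cand], `[[`, "w")
    ord <- do.call(order, as.data.frame(do.call(rbind, ws)))
    list(w = ws[[ord[1]]], f = sols[[cand[ord[1]]]]$f)
  }

  active <- seq_len(n)
  sol <- solveOn(active)
  pruned <- character(0)
  if (pruneBelow > 0 && n > 1) {
    drop <- sol$w < pruneBelow
    if (any(drop) && !all(drop)) {
      pruned <- ensemble@ids[active[drop]]
      active <- active[!drop]
      sol <- solveOn(active)
    }
  }
  w <- numeric(n)
  w[active] <- sol$w
  names(w) <- ensemble@ids
  calc <- obj$calc(w)
  res <- data.frame(name = od$name, kind = od$kind, observed = od$value,
                    calculated = calc, residual = calc - od$value,
                    weight = u, stringsAsFactors = FALSE)
  new("PopulationFit", weights = w, ssd = sol$f, residuals = res,
      pruned = pruned)
}

#' @rdname fitPopulations
#' @param fit a \linkS4class{PopulationFit}
#' @export
fitWeights <- function(fit) {
  stopifnot(is(fit, "PopulationFit"))
  fit@weights
}

#' Goodness-of-fit report per observable kind
#'
#' Root-mean-square residual per observable kind in native units, plus the
#' overall weighted SSD; the kinds partition the observable set.
#'
#' @param fit a \linkS4class{PopulationFit}
#' @param observed the \linkS4class{ObservedData} the fit was computed on
#' @return list with \code{rms} (named by kind), \code{ssd} and \code{n}
#'   (observable count per kind)
#' @export
goodnessReport <- function(fit, observed) {
  stopifnot(is(fit, "PopulationFit"), is(observed, "ObservedData"))
  r <- fit@residuals
  if (!identical(sort(r$name), sort(observed@observables$name)))
    stop("fit was not computed on this observed set")
  kinds <- unique(r$kind)
  rms <- vapply(kinds, function(k)
    sqrt(mean(r$residual[r$kind == k] ^ 2)), numeric(1))
  names(rms) <- kinds
  list(rms = rms, ssd = fit@ssd,
       n = vapply(kinds, function(k) sum(r$kind == k), numeric(1)))
}

#' Fitted population of a bioactive conformer family
#'
#' Sum of fitted weights over a named set of conformers, e.g. the family
#' matching the protein-bound pose; reports the molar fraction of the free
#' ligand pre-organized into it.
#'
#' @param fit a \linkS4class{PopulationFit}
#' @param bioactiveIds conformer ids of the bioactive family (subset of the
#'   fitted ensemble; empty set gives 0)
#' @return fraction in [0, 1]
#' @export
bioactiveFraction <- function(fit, bioactiveIds) {
  stopifnot(is(fit, "PopulationFit"))
  unknown <- setdiff(bioactiveIds, names(fit@weights))
  if (length(unknown))
    stop("unknown conformer id(s): ", paste(unknown, collapse = ", "))
  if (length(bioactiveIds) == 0) return(0)
  sum(fit@weights[bioactiveIds])
}
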