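test_that("noiseless synthetic populations are recovered to 1e-6", {
  syn <- genConformerEnsemble(c(0.7, 0.3), nConformers = 2, sigma = 0,
                              seed = 3)
  fit <- fitPopulations(syn$ensemble, syn$observed)
  expect_lt(max(abs(fitWeights(fit) - c(0.7, 0.3))), 1e-6)
  expect_lt(fit@ssd, 1e-12)
})

test_that("a single conformer gets weight one and its own residuals", {
  ens <- ConformerEnsemble(
    torsions = matrix(0, 1, 1),
    predicted = matrix(c(3, 5), nrow = 1,
                       dimnames = list(NULL, c("H1", "H2"))),
    obsKind = c("shift", "shift"))
  obs <- ObservedData(c("H1", "H2"), c("shift", "shift"), c(3.1, 5))
  fit <- fitPopulations(ens, obs)
  expect_equal(unname(fitWeights(fit)), 1)
  expect_equal(fit@ssd, 0.1 ^ 2, tolerance = 1e-9)
})

test_that("degenerate predictions resolve to the lexicographic tie rule", {
  ens <- ConformerEnsemble(
    torsions = matrix(c(0, 10), ncol = 1),
    predicted = matrix(c(3, 3), ncol = 1, dimnames = list(NULL, "H1")),
    obsKind = "shift")
  obs <- ObservedData("H1", "shift", 3)
  fit <- fitPopulations(ens, obs, pruneBelow = 0)
  expect_equal(unname(fitWeights(fit)), c(0, 1))
  expect_lt(fit@ssd, 1e-12)
})

test_that("fit rejects inconsistent inputs", {
  ens <- ConformerEnsemble(
    torsions = matrix(0, 1, 1),
    predicted = matrix(3, 1, 1, dimnames = list(NULL, "H1")),
    obsKind = "shift")
  expect_error(fitPopulations(ens, ObservedData("H9", "shift", 2)),
               "no conformer predictions")
  expect_error(ObservedData("H1", "shift", 2, weight = 0), "weight")
})

test_that("recovery error falls monotonically as observable noise shrinks", {
  sigmas <- c(0.2, 0.1, 0.05, 0)
  med <- vapply(sigmas, function(s) {
    errs <- vapply(1:50, function(seed) {
      syn <- genConformerEnsemble(c(0.7, 0.3), nConformers = 2, sigma = s,
                                  seed = seed)
      w <- fitWeights(fitPopulations(syn$ensemble, syn$observed,
                                     pruneBelow = 0))
      sum(abs(w - syn$provenance$trueWeights))
    }, numeric(1))
    median(errs)
  }, numeric(1))
  expect_true(all(diff(med) < 0))
  expect_lt(med[4], 1e-6)
})

test_that("solution never worsens any multi-start initial point", {
  ## non-convex case: distances with r^-6 averaging
  set.seed(21)
  n <- 4
  P <- cbind(matrix(runif(n * 3, 1, 9), n, 3),
             matrix(runif(n * 2, 2, 5), n, 2))
  colnames(P) <- c("H1", "H2", "H3", "d1", "d2")
  kinds <- c("shift", "shift", "shift", "distance", "distance")
  ens <- ConformerEnsemble(torsions = matrix(runif(n, -180, 180), n, 1),
                           predicted = P, obsKind = kinds)
  wTrue <- c(0.4, 0.3, 0.2, 0.1)
  y <- ensembleAverageObservables(ens, wTrue) + rnorm(5, 0, 0.05)
  obs <- ObservedData(colnames(P), kinds, y)
  fit <- fitPopulations(ens, obs, pruneBelow = 0)
  ssdOf <- function(w) {
    calc <- ensembleAverageObservables(ens, w)
    sum((calc - y) ^ 2)  # unit weights: shift/distance kind weights are 1
  }
  starts <- c(lapply(1:n, function(i) replace(numeric(n), i, 1)),
              list(rep(1 / n, n)))
  for (w0 in starts) expect_lte(fit@ssd, ssdOf(w0) + 1e-9)
})

test_that("an irrelevant conformer does not perturb the recovered pair", {
  syn <- genConformerEnsemble(c(0.7, 0.3), nConformers = 3, sigma = 0,
                              seed = 6)
  ## third conformer is a decoy with far-away predictions
  pred <- syn$ensemble@predicted
  pred[3, ] <- pred[3, ] + 20
  ens <- ConformerEnsemble(torsions = syn$ensemble@torsions,
                           ids = conformerIds(syn$ensemble),
                           predicted = pred, obsKind = syn$ensemble@obsKind)
  fit <- fitPopulations(ens, syn$observed)
  w <- fitWeights(fit)
  expect_lt(abs(w[["conf1"]] - 0.7), 0.01)
  expect_lt(abs(w[["conf2"]] - 0.3), 0.01)
  expect_lte(w[["conf3"]], 0.01)
})

test_that("goodness report gives per-kind RMS that partitions the set", {
  ens <- ConformerEnsemble(
    torsions = matrix(0, 1, 1),
    predicted = matrix(c(3, 5, 8), nrow = 1,
                       dimnames = list(NULL, c("H1", "H2", "J1"))),
    obsKind = c("shift", "shift", "coupling"))
  exact <- ObservedData(c("H1", "H2", "J1"),
                        c("shift", "shift", "coupling"), c(3, 5, 8))
  fitE <- fitPopulations(ens, exact)
  repE <- goodnessReport(fitE, exact)
  expect_equal(unname(repE$rms), c(0, 0))
  ## +0.1 ppm residual on one of two shifts: RMS = 0.1/sqrt(2)
  off <- ObservedData(c("H1", "H2", "J1"),
                      c("shift", "shift", "coupling"), c(3.1, 5, 8))
  fitO <- fitPopulations(ens, off)
  repO <- goodnessReport(fitO, off)
  expect_equal(repO$rms[["shift"]], 0.1 / sqrt(2), tolerance = 1e-9)
  expect_equal(repO$rms[["coupling"]], 0)
  expect_equal(sum(repO$n), 3)
  expect_error(goodnessReport(fitO, ObservedData("H1", "shift", 3)),
               "not computed")
})

test_that("bioactive fraction sums the fitted family weights", {
  ens <- ConformerEnsemble(
    torsions = matrix(c(0, 120), ncol = 1),
    predicted = matrix(c(2, 4), ncol = 1, dimnames = list(NULL, "H1")),
    obsKind = "shift")
  ## observed midpoint: two equally populated rotamer families
  fit <- fitPopulations(ens, ObservedData("H1", "shift", 3))
  expect_equal(bioactiveFraction(fit, "conf1"), 0.5, tolerance = 1e-6)
  expect_equal(bioactiveFraction(fit, c("conf1", "conf2")), 1,
               tolerance = 1e-9)
  expect_equal(bioactiveFraction(fit, character(0)), 0)
  expect_error(bioactiveFraction(fit, "confX"), "unknown conformer")
})
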