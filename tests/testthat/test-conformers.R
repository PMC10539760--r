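test_that("torsion distance is periodic, symmetric and zero on identity", {
  expect_equal(torsionDistance(c(10, -20), c(10, -20)), 0)
  expect_equal(torsionDistance(179, -179), 2)  # wraps, not 358
  set.seed(5)
  for (i in 1:10) {
    a <- runif(4, -180, 180)
    b <- runif(4, -180, 180)
    expect_equal(torsionDistance(a, b), torsionDistance(b, a))
  }
  expect_error(torsionDistance(c(1, 2), 3), "equal length")
})

toyCoords <- function() {
  m <- matrix(c(0, 0, 0,
                1.5, 0, 0,
                0, 1.2, 0,
                0.3, 0.4, 1.2), ncol = 3, byrow = TRUE)
  rownames(m) <- c("C1", "C2", "N1", "O1")
  m
}

rotZ <- function(th) matrix(c(cos(th), -sin(th), 0,
                              sin(th), cos(th), 0, 0, 0, 1), 3, 3)
rotX <- function(th) matrix(c(1, 0, 0, 0, cos(th), -sin(th),
                              0, sin(th), cos(th)), 3, 3)

test_that("Kabsch superposition is exact under rotation and translation", {
  a <- toyCoords()
  b <- a %*% rotZ(0.7) %*% rotX(-1.1)
  b <- sweep(b, 2, c(3, -2, 5), `+`)
  rownames(b) <- rownames(a)
  expect_equal(cartesianRmsd(a, a), 0)
  expect_lt(cartesianRmsd(a, b), 1e-9)
  ## label matching is by name, not order
  expect_lt(cartesianRmsd(a, b[c(3, 1, 4, 2), ]), 1e-9)
  expect_error(cartesianRmsd(a, unname(b)), "labels")
})

test_that("mirror images superpose only when improper rotations are allowed", {
  a <- toyCoords()
  m <- -a
  rownames(m) <- rownames(a)
  expect_lt(cartesianRmsd(a, m, allowMirror = TRUE), 1e-9)
  properRmsd <- cartesianRmsd(a, m)
  expect_gt(properRmsd, 0.1)
  ## brute-force oracle: best proper rotation over an Euler-angle grid
  ca <- sweep(a, 2, colMeans(a))
  cm <- sweep(m, 2, colMeans(m))
  best <- Inf
  for (a1 in seq(0, 2 * pi, length.out = 25))
    for (a2 in seq(0, pi, length.out = 13))
      for (a3 in seq(0, 2 * pi, length.out = 25)) {
        R3 <- rotZ(a1) %*% rotX(a2) %*% rotZ(a3)
        best <- min(best, sqrt(mean(rowSums((ca - cm %*% R3) ^ 2))))
      }
  expect_equal(properRmsd, best, tolerance = 0.05)
  expect_lte(properRmsd, best + 1e-9)  # ours is the true optimum
})

test_that("clustering merges duplicates and recovers planted wells", {
  ens <- ConformerEnsemble(torsions = matrix(c(10, 10, 120), ncol = 1))
  cl <- clusterConformers(ens, threshold = 30)
  expect_identical(max(cl$assignment), 2L)
  ## 500 conformers from three wells on one bond
  set.seed(8)
  wells <- c(-120, 0, 120)
  tor <- wells[sample.int(3, 500, replace = TRUE)] + rnorm(500, 0, 5)
  big <- ConformerEnsemble(torsions = matrix(tor, ncol = 1))
  clb <- clusterConformers(big, threshold = 30)
  reps <- clb$representatives
  expect_identical(nConformers(reps), 3L)
  got <- sort(reps@torsions[, 1])
  expect_true(all(abs(got - wells) < 5))
})

test_that("mirror-image representatives are discarded on request", {
  pair <- ConformerEnsemble(torsions = matrix(c(60, -60), ncol = 1))
  keepBoth <- clusterConformers(pair, threshold = 30)
  expect_identical(nConformers(keepBoth$representatives), 2L)
  dropped <- clusterConformers(pair, threshold = 30, discardMirrors = TRUE)
  expect_identical(nConformers(dropped$representatives), 1L)
  expect_identical(dropped$discarded, "conf2")
})

test_that("cluster partitions are invariant to conformer order", {
  set.seed(11)
  ens <- genWellEnsemble(n = 120, nBonds = 2, seed = 11)
  cl <- clusterConformers(ens, threshold = 30)
  perm <- sample.int(120)
  shuffled <- ConformerEnsemble(torsions = ens@torsions[perm, ],
                                ids = ens@ids[perm])
  cl2 <- clusterConformers(shuffled, threshold = 30)
  ## same partition up to relabeling: co-membership matrices agree
  co1 <- outer(cl$assignment, cl$assignment, `==`)
  a2 <- cl2$assignment[match(ens@ids, shuffled@ids)]
  co2 <- outer(a2, a2, `==`)
  expect_identical(co1, co2)
  expect_setequal(cl$representativeIds, cl2$representativeIds)
})

test_that("package-scale well ensembles reduce to 15-40 representatives", {
  ens <- genWellEnsemble(n = 1002, seed = 1)
  cl <- clusterConformers(ens, threshold = 30)
  expect_gte(nConformers(cl$representatives), 15)
  expect_lte(nConformers(cl$representatives), 40)
})

test_that("Boltzmann populations are normalized and gauge invariant", {
  expect_equal(boltzmannPopulations(c(0, 0), 300), c(0.5, 0.5))
  expect_equal(boltzmannPopulations(c(0, 0.6549487), 300), c(0.75, 0.25),
               tolerance = 1e-6)
  set.seed(2)
  e <- runif(6, 0, 5)
  expect_equal(boltzmannPopulations(e, 310),
               boltzmannPopulations(e + 100, 310), tolerance = 1e-12)
  expect_equal(sum(boltzmannPopulations(e, 310)), 1, tolerance = 1e-12)
  expect_error(boltzmannPopulations(numeric(0), 300), "empty")
  expect_error(boltzmannPopulations(c(0, Inf), 300), "finite")
})

test_that("ensemble averaging is linear for shifts and r^-6 for distances", {
  ens <- ConformerEnsemble(
    torsions = matrix(c(0, 120), ncol = 1),
    predicted = matrix(c(2, 4, 7, 9, 2, 4), nrow = 2,
                       dimnames = list(NULL, c("H1", "J12", "d13"))),
    obsKind = c("shift", "coupling", "distance"))
  one <- ensembleAverageObservables(ens, c(1, 0))
  expect_equal(unname(one), c(2, 7, 2))
  avg <- ensembleAverageObservables(ens, c(0.5, 0.5))
  expect_equal(unname(avg["H1"]), 3)
  expect_equal(unname(avg["J12"]), 8)
  expect_equal(unname(avg["d13"]), 2.239131, tolerance = 1e-6)
  avg3 <- ensembleAverageObservables(ens, c(0.5, 0.5),
                                     distanceAveraging = "r3")
  expect_equal(unname(avg3["d13"]),
               (0.5 * 2 ^ -3 + 0.5 * 4 ^ -3) ^ (-1 / 3), tolerance = 1e-9)
  expect_error(ensembleAverageObservables(ens, c(0.9, 0.2)), "sum to 1")
  bad <- ConformerEnsemble(torsions = matrix(0, 1, 1))
  expect_error(ensembleAverageObservables(bad, 1), "no predicted")
})
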