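test_that("geometric ladders hit their endpoints with a constant ratio", {
  l12 <- buildLadder(300, 1263, 12)
  expect_equal(l12[1], 300)
  expect_equal(l12[12], 1263)
  expect_lt(diff(range(diff(log(l12)))), 1e-9)
  l20 <- buildLadder(300, 3302, 20)
  expect_equal(l20[c(1, 20)], c(300, 3302))
  expect_equal(buildLadder(300, 300, 5), rep(300, 5))
  expect_equal(buildLadder(300, 900, 1), 300)
  expect_error(buildLadder(300, 900, 0), "positive integer")
  expect_error(buildLadder(900, 300, 4), "tMax")
})

test_that("swap probability formula matches its closed form and frequency", {
  expect_equal(exchangeProbability(3.2, 3.2, 300, 1300), 1)
  expect_equal(exchangeProbability(25, 0, 500, 500), 1)
  ## cold replica low, hot replica high: always swap
  expect_equal(exchangeProbability(25, 0, 300, 3300), 1)
  ## the unfavorable direction has the Boltzmann-factor probability
  R <- GAS_CONSTANT_KCAL
  p <- exp((1 / (R * 300) - 1 / (R * 600)) * (0 - 1))
  expect_equal(exchangeProbability(0, 1, 300, 600), p)
  set.seed(1)
  draws <- runif(1e5)
  emp <- mean(exchangeAccept(0, 1, 300, 600, draws))
  se <- sqrt(p * (1 - p) / 1e5)
  expect_lt(abs(emp - p), 3 * se)
})

test_that("trajectories are bit-identical under a fixed seed", {
  pot <- genTorsionPotential("desmethyl")
  ladder <- buildLadder(300, 900, 4)
  a <- runRex(pot, ladder, sweeps = 2000, startAngle = 45, seed = 99)
  b <- runRex(pot, ladder, sweeps = 2000, startAngle = 45, seed = 99)
  expect_identical(a@angles, b@angles)
  expect_identical(a@walkers, b@walkers)
  expect_identical(a@exchangeLog, b@exchangeLog)
  c <- runRex(pot, ladder, sweeps = 2000, startAngle = 45, seed = 100)
  expect_false(identical(a@angles, c@angles))
})

test_that("histograms count retained samples and find the sampled modes", {
  ## constant trajectory: a single nonzero bin
  const <- new("TorsionTrajectory",
               angles = matrix(90, 50, 1), walkers = matrix(1L, 50, 1),
               ladder = 300, exchangeLog = data.frame(), seed = 1,
               startAngle = 90, stepDeg = 10, exchangeInterval = 10)
  h <- torsionHistogram(const, bins = 36, burnIn = 0)
  expect_identical(sum(h$count > 0), 1L)
  expect_equal(sum(h$count), 50)
  ## subsampling to a fixed frame count
  pot <- genTorsionPotential("flexible_threefold")
  traj <- runRex(pot, 300, sweeps = 20000, startAngle = 60, seed = 3)
  h2 <- torsionHistogram(traj, bins = 72, burnIn = 0.1, nFrames = 1002)
  expect_equal(sum(h2$count), 1002)
  ## three modes separated by about 120 degrees
  h3 <- torsionHistogram(traj, bins = 72, burnIn = 0.1)
  wells <- barrierReport(pot)$wells$minimum
  top <- h3$mid[order(h3$count, decreasing = TRUE)][1:20]
  perdist <- function(a, b) abs((a - b + 180) %% 360 - 180)
  nearest <- vapply(top, function(a) min(perdist(a, wells)), numeric(1))
  expect_true(all(nearest < 20))
  expect_error(torsionHistogram(traj, bins = 1), "bins")
})

test_that("free-energy inversion reproduces count ratios and masks empties", {
  h <- data.frame(mid = c(-90, 90), count = c(300, 300))
  fe <- freeEnergyProfile(h, 300)
  expect_equal(diff(fe$dG), 0)
  h2 <- data.frame(mid = c(-90, 0, 90), count = c(300, 0, 100))
  fe2 <- freeEnergyProfile(h2, 300)
  expect_equal(fe2$dG[3] - fe2$dG[1], 0.6549, tolerance = 1e-3)
  expect_true(is.na(fe2$dG[2]))
  expect_error(freeEnergyProfile(data.frame(mid = 0, count = 0), 300),
               "all-zero")
})

test_that("barrier report locates preset minima and barrier heights", {
  ## independent oracle: dense periodic grid scan of the evaluated potential
  pot <- genTorsionPotential("hindered_biaryl")
  phi <- seq(-180, 180 - 0.001, by = 0.001)
  v <- potentialEnergy(pot, phi)
  isMax <- v > c(v[length(v)], v[-length(v)]) & v > c(v[-1], v[1])
  gridOracle <- min(v[isMax]) - min(v)  # lower saddle above the global min
  rep <- barrierReport(pot)
  expect_equal(gridOracle, 20, tolerance = 0.01)
  expect_equal(rep$headline, gridOracle, tolerance = 1e-4)
  expect_equal(sort(rep$wells$minimum), sort(c(-1, 1) * 91.365),
               tolerance = 0.01)
  expect_lt(barrierReport(genTorsionPotential("desmethyl"))$headline, 6)
  ## single-well pure cosine: one minimum, peak-to-trough barrier = V1
  single <- genTorsionPotential(data.frame(n = 1, Vn = 4, gamma = 0))
  rs <- barrierReport(single)
  expect_identical(nrow(rs$wells), 1L)
  expect_equal(rs$wells$barrier, 4, tolerance = 1e-6)
  ## flat potential: degenerate, zero barriers
  flat <- genTorsionPotential(data.frame(n = 1, Vn = 0, gamma = 0))
  expect_true(barrierReport(flat)$degenerate)
})

test_that("threefold preset has three equal minima and periodic energies", {
  pot <- genTorsionPotential("flexible_threefold")
  rep <- barrierReport(pot)
  expect_identical(nrow(rep$wells), 3L)
  expect_lt(diff(range(rep$wells$vMin)), 1e-9)
  expect_equal(rep$wells$barrier, rep(3, 3), tolerance = 1e-6)
  phi <- seq(-180, 179, by = 7.3)
  for (p in list(pot, genTorsionPotential("hindered_biaryl"))) {
    expect_equal(potentialEnergy(p, phi), potentialEnergy(p, phi + 360),
                 tolerance = 1e-12)
  }
  expect_error(genTorsionPotential("no_such_preset"), "unknown preset")
})

test_that("a single cold replica stays trapped; a hot ladder equilibrates", {
  pot <- genTorsionPotential("hindered_biaryl")
  trapped <- runRex(pot, 300, sweeps = 20000, startAngle = 90,
                    stepDeg = 10, seed = 7)
  d <- ergodicityDiagnostics(trapped, pot)
  startWell <- which.min(abs(d$wells$wells$minimum - 90))
  expect_equal(d$occupancies[startWell], 1)
  expect_equal(d$occupancies[-startWell], 0)
  expect_false(d$ergodic)
  hot <- runRex(pot, buildLadder(300, 3300, 12), sweeps = 50000,
                startAngle = 90, seed = 7)
  dh <- ergodicityDiagnostics(hot, pot)
  expect_true(dh$ergodic)
  expect_equal(unname(dh$occupancies), c(0.5, 0.5), tolerance = 0.1)
})

test_that("long-run occupancies match Boltzmann basin weights", {
  ## asymmetric double well: the sin term deepens one well
  pot <- genTorsionPotential(data.frame(n = c(2, 1), Vn = c(5, 0.5),
                                        gamma = c(0, 90)))
  traj <- runRex(pot, 300, sweeps = 5e5, startAngle = -90, seed = 13)
  d <- ergodicityDiagnostics(traj, pot, burnIn = 0.1)
  expect_gt(d$transitions, 30)
  ## binomial 3-sigma with the transition count as the effective n
  sigma <- sqrt(d$boltzmann[1] * (1 - d$boltzmann[1]) / d$transitions)
  expect_lt(abs(d$occupancies[1] - d$boltzmann[1]), 3 * sigma + 0.02)
})

test_that("raising the ladder top does not reduce barrier crossings", {
  pot <- genTorsionPotential("hindered_biaryl")
  med <- vapply(c(600, 3300), function(tmax) {
    trans <- vapply(1:20, function(s) {
      traj <- runRex(pot, buildLadder(300, tmax, 6), sweeps = 4000,
                     startAngle = 90, seed = s)
      ergodicityDiagnostics(traj, pot)$transitions
    }, numeric(1))
    median(trans)
  }, numeric(1))
  expect_lte(med[1], med[2])
  expect_gt(med[2], 0)
})

test_that("radial series maps sweeps to radius and flags the endpoints", {
  const <- new("TorsionTrajectory",
               angles = matrix(45, 30, 1), walkers = matrix(1L, 30, 1),
               ladder = 300, exchangeLog = data.frame(), seed = 1,
               startAngle = 45, stepDeg = 10, exchangeInterval = 10)
  rs <- radialSeries(const)
  expect_identical(nrow(rs), 30L)
  expect_equal(unique(rs$angle), 45)
  expect_true(all(diff(rs$radius) > 0))
  expect_identical(which(rs$endpoint), c(1L, 30L))
  expect_identical(rs$sweep[1], 0)
})

test_that("run and report validation reject degenerate inputs", {
  pot <- genTorsionPotential("desmethyl")
  expect_error(runRex(pot, 300, sweeps = 0), "sweeps")
  expect_error(runRex(pot, 300, sweeps = 10, stepDeg = 0), "stepDeg")
  traj <- runRex(pot, 300, sweeps = 10, seed = 1)
  expect_error(baseSeries(traj, burnIn = 1), "burnIn")
})
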