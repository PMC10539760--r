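test_that("integral normalization calibrates the reference to 100", {
  n <- normalizeIntegrals(200, 50)
  expect_equal(n$reference, 100)
  expect_equal(n$exchanged, 25)
  expect_equal(n$fraction, 0.25)
  expect_equal(normalizeIntegrals(100, 0)$fraction, 0)
  ## homogeneity: common scaling of both raw integrals changes nothing
  a <- normalizeIntegrals(137, 41)
  b <- normalizeIntegrals(137 * 7.3, 41 * 7.3)
  expect_equal(a, b)
  expect_error(normalizeIntegrals(0, 10), "nonzero")
})

test_that("equal-population build-up model has the right limits and values", {
  expect_equal(buildupModel(1.386, 0.5), 0.3749632, tolerance = 1e-6)
  expect_equal(buildupModel(5, 0), 0)
  expect_equal(buildupModel(1.386, 1e6), 0.5)
  expect_error(buildupModel(1, -0.1), "mixing")
  expect_error(buildupModel(-1, 0.1), "k must")
  ## T1 damping multiplies the undamped model
  expect_equal(buildupModel(2, 0.4, t1 = 1.5),
               buildupModel(2, 0.4) * exp(-0.4 / 1.5))
  ## unequal-population generalization reduces to the 1:1 model
  expect_equal(buildupModelUnequal(2 * 1.386, MIX_TIMES, pB = 0.5),
               buildupModel(1.386, MIX_TIMES))
})

test_that("rate fits recover noiseless generator truth to high precision", {
  for (k in c(0.5, 1.386, 5)) {
    fit <- fitRate(data.frame(mixing_time_s = MIX_TIMES,
                              intensity = buildupModel(k, MIX_TIMES)))
    expect_lt(abs(exchangeRate(fit) - k) / k, 1e-6)
    expect_true(fit@converged)
  }
  fit <- fitRate(data.frame(mixing_time_s = MIX_TIMES,
                            intensity = buildupModel(1.3863, MIX_TIMES)))
  expect_equal(halfLife(fit), 0.500, tolerance = 1e-4)
})

test_that("rate fit flags the degenerate and invalid inputs", {
  zero <- fitRate(data.frame(mixing_time_s = MIX_TIMES,
                             intensity = rep(0, 8)))
  expect_equal(exchangeRate(zero), 0)
  expect_true(zero@noExchange)
  expect_error(fitRate(data.frame(mixing_time_s = c(0.1, 0.2),
                                  intensity = c(0, 0.1))), "at least 3")
  expect_error(fitRate(data.frame(mixing_time_s = c(0.1, 0.2, 0.2),
                                  intensity = c(0, 0.1, 0.1))),
               "strictly increasing")
})

test_that("ignoring T1 decay biases the fitted rate low", {
  y <- buildupModel(1.5, MIX_TIMES, t1 = 1)
  kNoT1 <- exchangeRate(fitRate(data.frame(mixing_time_s = MIX_TIMES,
                                           intensity = y)))
  kT1 <- exchangeRate(fitRate(data.frame(mixing_time_s = MIX_TIMES,
                                         intensity = y),
                              modelTag = "t1", t1 = 1))
  expect_lt(kNoT1, 1.5)          # bias sign: low
  expect_equal(kT1, 1.5, tolerance = 1e-6)  # matched model recovers truth
})

test_that("Arrhenius regression recovers collinear rates exactly", {
  truth <- arrheniusTruth(19.9, kRef = 1.386, tRef = 300)
  k <- arrheniusRate(truth, c(300, 305, 310))
  fit <- suppressWarnings(
    fitArrhenius(data.frame(temperature_K = c(300, 305, 310), k = k)))
  expect_equal(activationEnergy(fit), 19.9, tolerance = 1e-9)
  expect_equal(fit@lnA, truth@lnA, tolerance = 1e-9)
  ## two points: exact two-point solution
  fit2 <- suppressWarnings(
    fitArrhenius(data.frame(temperature_K = c(300, 310), k = k[c(1, 3)])))
  expect_equal(activationEnergy(fit2), 19.9, tolerance = 1e-9)
})

test_that("Arrhenius fit validates input and warns on narrow spans", {
  expect_warning(
    fitArrhenius(data.frame(temperature_K = c(300, 305, 310),
                            k = c(1, 2, 4))),
    "narrow")
  expect_error(fitArrhenius(data.frame(temperature_K = c(300, 310),
                                       k = c(1, -1))), "> 0")
  expect_error(fitArrhenius(data.frame(temperature_K = c(300, 300),
                                       k = c(1, 2))), "duplicate")
})

test_that("rescaling all rates shifts lnA but not the activation energy", {
  truth <- arrheniusTruth(12, kRef = 10, tRef = 300,
                          temperatures = c(280, 300, 320, 340))
  k <- arrheniusRate(truth, truth@temperatures)
  f1 <- fitArrhenius(data.frame(temperature_K = truth@temperatures, k = k))
  f2 <- fitArrhenius(data.frame(temperature_K = truth@temperatures,
                                k = 100 * k))
  expect_equal(activationEnergy(f1), activationEnergy(f2), tolerance = 1e-9)
  expect_equal(f2@lnA - f1@lnA, log(100), tolerance = 1e-9)
})

test_that("noisy narrow-span Arrhenius errors are finite and flagged", {
  truth <- arrheniusTruth(19.9, kRef = 1.386, tRef = 300)
  temps <- c(300, 305, 310)
  kTrue <- arrheniusRate(truth, temps)
  set.seed(42)
  errs <- replicate(100, {
    k <- kTrue * exp(rnorm(3, 0, 0.01))
    fit <- suppressWarnings(
      fitArrhenius(data.frame(temperature_K = temps, k = k)))
    expect_true(fit@narrowSpan)
    abs(activationEnergy(fit) - 19.9) / 19.9
  })
  expect_true(is.finite(median(errs)))
})

test_that("Eyring conversions give the textbook barriers and invert", {
  expect_equal(eyringBarrier(log(2) / 0.5, 300), 17.37, tolerance = 1e-3)
  expect_equal(eyringBarrier(log(2) / 1e-9, 300), 5.429, tolerance = 1e-3)
  ## dG = 5 kcal/mol at 300 K corresponds to a ~0.49 ns half-life
  expect_equal(log(2) / eyringRate(5, 300), 4.868e-10, tolerance = 1e-3)
  ## mutual inverses
  for (k in c(1e-3, 1.386, 1e6)) {
    expect_equal(eyringRate(eyringBarrier(k, 300), 300), k,
                 tolerance = 1e-9)
  }
  ## strictly decreasing in k at fixed T
  ks <- 10 ^ seq(-3, 9, by = 1)
  expect_true(all(diff(eyringBarrier(ks, 300)) < 0))
  expect_error(eyringBarrier(0, 300), "k must")
})

test_that("exchange-regime classification matches the rotamer phenomenology", {
  expect_identical(classifyExchangeRegime(1.386, 100), "slow")
  expect_identical(classifyExchangeRegime(1e9, 100), "fast")
  expect_identical(classifyExchangeRegime(coalescenceRate(100), 100),
                   "intermediate")
})

test_that("EXSY CSV round trip preserves the dataset", {
  truth <- arrheniusTruth(19.9, kRef = 1.386, tRef = 300)
  ds <- genExsyDataset(truth, sigma = 0.01, seed = 4)
  tmp <- tempfile(fileext = ".csv")
  writeEXSYCsv(ds, tmp)
  back <- readEXSYCsv(tmp)
  expect_equal(back@data$intensity, ds@data$intensity, tolerance = 1e-12)
  expect_equal(exsyTemperatures(back), c(300, 305, 310))
})
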