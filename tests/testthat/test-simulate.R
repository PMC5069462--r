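test_that("the same seed reproduces the simulation exactly", {
  d <- simDesign(scenarioLibrary("eth_dose")$signatures["Eth"],
    doses = c(0, 2), timesMin = 30, cellsPerCondition = 4L, replicates = 2L,
    grid = seq(600, 1800, length.out = 200L), seed = 11L
  )
  s1 <- simulateRamanome(d)
  s2 <- simulateRamanome(d)
  expect_identical(scrs(s1$ramanome), scrs(s2$ramanome))
  expect_identical(s1$groundTruth, s2$groundTruth)
})

test_that("null signatures are indistinguishable from control by ANOSIM", {
  null <- stressorSignature("Eth",
    c(nucleic_acid = 0, protein = 0, lipid = 0, carbohydrate = 0),
    doseRef = 5
  )
  d <- simDesign(list(null),
    doses = c(0, 5), timesMin = 30, cellsPerCondition = 10L, replicates = 2L,
    grid = seq(600, 1800, length.out = 300L), seed = 5L
  )
  pp <- preprocessRamanome(simulateRamanome(d)$ramanome)
  lab <- cellData(pp)$stressor != "none"
  a <- anosimTest(pp, lab, nPerm = 199, seed = 5)
  expect_lt(abs(a$R), 0.1)
})

test_that("a planted amplitude factor is recovered on corrected spectra", {
  # nucleic-acid factor 0.5 at the queried (dose, time): build a signature
  # whose 782 band halves, with no other variation sources
  sig <- stressorSignature("Eth",
    c(nucleic_acid = 0, protein = 0, lipid = 0, carbohydrate = 0),
    bandOverrides = c("782" = log(0.5)),
    template = list(t = c(0, 30), h = c(0, 1)), altWeight = 0,
    transientWeight = 0, timeWarpSpread = 0,
    heterogeneityScale = setNames(rep(1e-9, 5), c(
      "nucleic_acid", "protein", "lipid", "carbohydrate", "other"
    )),
    doseTemplate = "linear", doseRef = 5
  )
  grid <- seq(600, 1800, length.out = 790L)
  # isolated bands so the baseline under the 782 peak is unbiased
  peaks <- rbind(
    peakSpec(782, 8, baseAmplitude = 1, category = "nucleic_acid"),
    peakSpec(1002, 8, baseAmplitude = 1, category = "protein"),
    peakSpec(1445, 8, baseAmplitude = 1, category = "lipid")
  )
  d <- simDesign(list(sig),
    doses = c(0, 5), timesMin = 30, cellsPerCondition = 8L, replicates = 1L,
    noiseSd = 0.005, residSd = 0, grid = grid, peaks = peaks, seed = 2L
  )
  raw <- simulateRamanome(d)$ramanome
  cd <- cellData(raw)
  corrected <- t(apply(scrs(raw), 1L, function(y) baselineALS(y)$corrected))
  i782 <- matchBands(grid, 782)
  ratio <- mean(corrected[cd$stressor == "Eth", i782]) /
    mean(corrected[cd$stressor == "none", i782])
  expect_equal(ratio, 0.5, tolerance = 0.05)
})

test_that("scenario layouts match the study designs", {
  d <- scenarioLibrary("eth_dose")
  expect_setequal(d$doses, c(0, 0.5, 1, 2, 3, 5))
  expect_identical(d$cellsPerCondition, 20L)
  expect_identical(d$replicates, 3L)
  cd <- cellData(simulateRamanome(
    scenarioLibrary("eth_dose", cellsPerCondition = 2, replicates = 2)
  )$ramanome)
  expect_identical(sort(unique(cd$dose)), c(0, 0.5, 1, 2, 3, 5))

  d <- scenarioLibrary("eth_time")
  expect_identical(
    sort(d$timesMin),
    c(0, 5, 10, 20, 30, 60, 180, 300, 480, 1200)
  )

  d <- scenarioLibrary("six_stressors", cellsPerCondition = 2, replicates = 1)
  cd <- cellData(simulateRamanome(d)$ramanome)
  expect_setequal(unique(cd$stressor), c("Eth", "nBut", "Amp", "Kan", "Cu", "Cr", "none"))
  expect_identical(sort(unique(cd$time_min)), c(5, 10, 20, 30, 60, 180, 300))

  d <- scenarioLibrary("kan_resistance", cellsPerCondition = 2, replicates = 1)
  cd <- cellData(simulateRamanome(d)$ramanome)
  expect_setequal(unique(cd$strain), c("WT", "Kans", "Kanr"))
  expect_error(scenarioLibrary("unknown"))
})

test_that("ground truth aligns with cells and sums category amplitudes", {
  d <- simDesign(scenarioLibrary("eth_dose")$signatures["Eth"],
    doses = c(0, 5), timesMin = 30, cellsPerCondition = 5L, replicates = 1L,
    grid = seq(600, 1800, length.out = 200L), seed = 4L
  )
  sim <- simulateRamanome(d)
  expect_identical(sim$groundTruth$cell_id, cellData(sim$ramanome)$cell_id)
  expect_true(all(sim$groundTruth$lipid > 0))
  # stressed cells have higher lipid ground truth (positive lipid effect)
  cd <- cellData(sim$ramanome)
  expect_gt(
    mean(sim$groundTruth$lipid[cd$stressor == "Eth"]),
    mean(sim$groundTruth$lipid[cd$stressor == "none"])
  )
})

test_that("the effect factor is 1 at zero dose or time zero", {
  sig <- scenarioLibrary("eth_dose")$signatures$Eth
  peaks <- defaultPeakTable()
  expect_equal(ramanome:::.effectFactor(sig, peaks, 0, 60), rep(1, nrow(peaks)))
  expect_equal(ramanome:::.effectFactor(sig, peaks, 5, 0), rep(1, nrow(peaks)))
  # monotone in dose at fixed time
  f1 <- ramanome:::.effectFactor(sig, peaks, 1, 30)
  f3 <- ramanome:::.effectFactor(sig, peaks, 3, 30)
  f5 <- ramanome:::.effectFactor(sig, peaks, 5, 30)
  expect_true(all(abs(log(f3)) >= abs(log(f1)) - 1e-12))
  expect_true(all(abs(log(f5)) >= abs(log(f3)) - 1e-12))
})
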