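test_that("cropping keeps the closed interval and is idempotent", {
  r <- tinyRamanome(n = 2, b = 61) # grid 600..1800 step 20
  c1 <- cropSpectra(r, 700, 1500)
  expect_true(all(wavenumbers(c1) >= 700 & wavenumbers(c1) <= 1500))
  expect_identical(range(wavenumbers(c1)), c(700, 1500)) # closed bounds kept
  c2 <- cropSpectra(c1, 700, 1500)
  expect_equal(scrs(c2), scrs(c1))
  expect_error(cropSpectra(r, 2000, 2100), "overlap")
})

test_that("ALS baseline removes smooth trends and preserves peak height", {
  grid <- seq(600, 1800, length.out = 600)
  x <- (grid - 600) / 1200
  ramp <- 2 + 3 * x
  out <- baselineALS(ramp)
  expect_lt(max(abs(out$corrected)) / diff(range(ramp)), 1e-3)

  h <- 2
  peak <- h * exp(-(grid - 1200)^2 / (2 * 12^2))
  quad <- 1 + 2 * x - 1.5 * x^2
  rec <- baselineALS(peak + quad)$corrected
  expect_lt(abs(max(rec) - h) / h, 0.05)

  expect_equal(baselineALS(rep(0, 100))$corrected, rep(0, 100))
  expect_error(baselineALS(c(rep(1, 50), NA)), "non-finite")
  expect_error(baselineALS(rep(1, 10)), "16")
})

test_that("resampling interpolates linearly and refuses extrapolation", {
  r <- tinyRamanome(n = 2, b = 50)
  same <- resampleToGrid(r, wavenumbers(r))
  expect_equal(scrs(same), scrs(r))

  # linear data are reproduced exactly anywhere inside the range
  grid <- seq(600, 1800, length.out = 50)
  lin <- Ramanome(outer(c(1, 2), 0.01 * grid), grid,
    cellData(r)[, c("cell_id", "stressor", "dose", "dose_unit", "time_min", "replicate")]
  )
  target <- seq(650, 1750, length.out = 37)
  expect_equal(scrs(resampleToGrid(lin, target)), outer(c(1, 2), 0.01 * target),
    ignore_attr = TRUE
  )

  # downsampled Gaussian stays within the analytic interpolation error bound
  fine <- seq(600, 1800, length.out = 1201)
  gauss <- function(w) exp(-(w - 1200)^2 / (2 * 15^2))
  rg <- Ramanome(matrix(gauss(fine), 1), fine, cellData(r)[1, ])
  coarse <- seq(610, 1790, length.out = 200)
  got <- as.numeric(scrs(resampleToGrid(rg, coarse)))
  hstep <- diff(fine)[1]
  maxCurv <- max(abs((gauss(fine) - 2 * gauss(fine + hstep) + gauss(fine + 2 * hstep)) / hstep^2))
  expect_lt(max(abs(got - gauss(coarse))), maxCurv * hstep^2 / 8 + 1e-12)

  expect_error(resampleToGrid(r, c(500, 700)), "extrapolation")
})

test_that("normalization yields unit norm and is gain-invariant", {
  r <- tinyRamanome(n = 3, b = 30, gain = c(1, 5, 10))
  l2 <- normalizeSpectra(r, "l2")
  expect_equal(unname(sqrt(rowSums(scrs(l2)^2))), rep(1, 3))
  expect_equal(scrs(l2)[1, ], scrs(l2)[2, ], ignore_attr = TRUE)
  ar <- normalizeSpectra(r, "area")
  expect_equal(unname(rowSums(scrs(ar))), rep(1, 3))
  z <- tinyRamanome(n = 1, b = 30, gain = 0)
  expect_error(normalizeSpectra(z, "l2"), "all-zero")
})

test_that("the preprocessing pipeline is invariant to per-cell laser gain", {
  design <- simDesign(scenarioLibrary("eth_dose")$signatures["Eth"],
    doses = c(0, 5), timesMin = 30, cellsPerCondition = 3L, replicates = 1L,
    grid = seq(600, 1800, length.out = 300L), seed = 7L
  )
  raw <- simulateRamanome(design)$ramanome
  gained <- Ramanome(scrs(raw) * c(1, 2, 5, 0.5, 1, 3), wavenumbers(raw), cellData(raw))
  p1 <- preprocessRamanome(raw)
  p2 <- preprocessRamanome(gained)
  expect_equal(scrs(p1), scrs(p2), tolerance = 1e-8)
})

test_that("cells below the SNR threshold are dropped and logged", {
  design <- simDesign(scenarioLibrary("eth_dose")$signatures["Eth"],
    doses = c(0, 5), timesMin = 30, cellsPerCondition = 10L, replicates = 1L,
    seed = 3L
  )
  raw <- simulateRamanome(design)$ramanome
  m <- scrs(raw)
  set.seed(1)
  m[1, ] <- 1 + rnorm(ncol(m), 0, 1e-4) # flat scan: no Raman signal at all
  noisy <- Ramanome(m, wavenumbers(raw), cellData(raw))
  pp <- preprocessRamanome(noisy, preprocessConfig(qcMinSnr = 5))
  expect_identical(ncol(pp), ncol(noisy) - 1L)
  dropped <- attr(pp, "dropped")
  expect_identical(dropped$cell_id, cellData(noisy)$cell_id[1])
  expect_identical(processingState(pp), "preprocessed")
  expect_true(min(scrs(pp)) >= -1e-9)
  expect_error(
    preprocessRamanome(noisy, preprocessConfig(qcMinSnr = 1e9)),
    "all cells"
  )
})
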