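test_that("D-value profiles are zero at t = 0, zero for identical groups, antisymmetric", {
  r <- tinyRamanome(n = 6, b = 30, gain = c(1, 1.1, 0.9, 1, 1.05, 0.95), state = "preprocessed")
  times <- c(0, 10, 30)
  prof <- dValueProfiles(list(r, r, r), list(r, r, r), times)
  expect_true(all(prof$d == 0))

  shifted <- Ramanome(scrs(r) + 0.02, wavenumbers(r), cellData(r), "raw")
  p1 <- dValueProfiles(list(r, shifted, shifted), list(r, r, r), times)
  expect_true(all(p1$d[, 1] == 0)) # defined zero at onset
  p2 <- dValueProfiles(list(r, r, r), list(r, shifted, shifted), times)
  expect_equal(p2$d[, -1], -p1$d[, -1])
})

test_that("nucleic-acid suppression produces a decreasing 782 profile", {
  sig <- stressorSignature("Eth",
    c(nucleic_acid = -2.5, protein = 0, lipid = 0, carbohydrate = 0),
    template = list(t = c(0, 60), h = c(0, 1)), altWeight = 0,
    transientWeight = 0, timeWarpSpread = 0, doseTemplate = "linear", doseRef = 5
  )
  sig$heterogeneityScale[] <- 0.05
  d <- simDesign(list(sig),
    doses = c(0, 5), timesMin = c(0, 15, 30, 60),
    cellsPerCondition = 25L, replicates = 1L, noiseSd = 0.02, residSd = 0.02,
    grid = seq(600, 1800, length.out = 400L), seed = 6L
  )
  pp <- preprocessRamanome(simulateRamanome(d)$ramanome)
  cd <- cellData(pp)
  times <- c(0, 15, 30, 60)
  sl <- lapply(times, function(t) pp[, cd$stressor == "Eth" & cd$time_min == t])
  cl <- lapply(times, function(t) pp[, cd$stressor == "none" & cd$time_min == t])
  prof <- dValueProfiles(sl, cl, times)
  row782 <- prof$d[matchBands(prof$wavenumber, 782), ]
  expect_true(all(diff(row782) < 0))
})

test_that("marker selection agrees with a brute-force rule over the band x time grid", {
  set.seed(61)
  grid <- seq(640, 1800, length.out = 60)
  times <- c(0, 10, 30)
  mk <- function(shift) {
    m <- matrix(abs(rnorm(12 * 60, 5, 0.2)), 12)
    m[, 1:10] <- m[, 1:10] + shift
    asPreprocessed(m, grid)
  }
  ctrl <- lapply(times, function(t) mk(0))
  strs <- lapply(seq_along(times), function(j) mk(c(0, 2, 3)[j]))
  prof <- dValueProfiles(strs, ctrl, times)
  tests <- lapply(seq_along(times), function(j) {
    bandTests(strs[[j]], ctrl[[j]], alpha = 0.01)
  })
  got <- significantBands(prof, tests, minTimes = 2)

  # independent re-implementation of the persistence rule
  signs <- sapply(tests, function(tt) tt$sign)
  keep <- rowSums(signs != 0) >= 2
  expect_setequal(got$wavenumber, prof$wavenumber[keep])
  expect_equal(got$importance, sort(apply(abs(prof$d[keep, ]), 1, max), decreasing = TRUE),
    ignore_attr = TRUE
  )

  # ordering is invariant to band input order (reverse the grid blocks)
  expect_true(all(diff(got$importance) <= 1e-12))
})

test_that("no significant bands yields an empty set with a warning", {
  r <- tinyRamanome(n = 5, b = 20, gain = rep(1, 5), state = "preprocessed")
  times <- c(0, 10)
  prof <- dValueProfiles(list(r, r), list(r, r), times)
  tests <- list(bandTests(r, r), bandTests(r, r))
  expect_warning(mk <- significantBands(prof, tests), "no band")
  expect_identical(nrow(mk), 0L)
})

test_that("silhouette matches the brute-force formula on enumerable toys", {
  set.seed(62)
  x <- rbind(
    matrix(rnorm(8, 0, 0.1), 4),
    matrix(rnorm(8, 5, 0.1), 4)
  )
  cl <- rep(1:2, each = 4)
  ours <- ramanome:::.meanSilhouette(dist(x), cl)
  expect_equal(ours, bruteSilhouette(x, cl), tolerance = 1e-12)

  # perfectly separated equal-size clusters on 6 points
  y <- matrix(c(0, 0.1, 0.2, 10, 10.1, 10.2), ncol = 1)
  cl6 <- rep(1:2, each = 3)
  expect_equal(
    ramanome:::.meanSilhouette(dist(y), cl6),
    bruteSilhouette(y, cl6),
    tolerance = 1e-12
  )
})

test_that("temporal clustering recovers planted up/down archetypes", {
  set.seed(63)
  times <- c(0, 10, 30, 60, 180)
  up <- c(0, 0.2, 0.5, 0.8, 1)
  down <- -up
  d <- rbind(
    matrix(rep(up, each = 10), 10) + rnorm(50, 0, 0.05),
    matrix(rep(down, each = 8), 8) + rnorm(40, 0, 0.05)
  )
  prof <- structure(
    list(
      d = d, times = times,
      wavenumber = seq(700, 1700, length.out = 18), stressor = "Eth"
    ),
    class = "DValueProfile"
  )
  tc <- clusterTemporal(prof, kRange = 2:4, seed = 1)
  expect_identical(tc$k, 2L)
  expect_gt(tc$silhouette, 0.5)
  expect_identical(length(unique(tc$cluster[1:10])), 1L)
  expect_identical(length(unique(tc$cluster[11:18])), 1L)
  expect_false(tc$cluster[1] == tc$cluster[11])

  # cluster memberships are stable across seeds (adjusted-Rand proxy:
  # identical partitions up to label swap)
  parts <- lapply(1:10, function(s) clusterTemporal(prof, kRange = 2:4, seed = s)$cluster)
  agree <- vapply(parts, function(p) {
    tab <- table(p, tc$cluster)
    (sum(apply(tab, 1, max))) / length(p)
  }, numeric(1))
  expect_true(mean(agree >= 0.95) >= 0.9)

  flat <- prof
  flat$d <- matrix(rep(up, each = 18), 18)
  expect_error(clusterTemporal(flat, kRange = 2:3, seed = 1), "no temporal structure")
})
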