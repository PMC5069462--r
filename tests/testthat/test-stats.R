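test_that("ANOSIM matches the hand-enumerated toy exactly", {
  x <- matrix(c(0, 1, 10, 11))
  g <- c("a", "a", "b", "b")
  res <- anosimTest(x, g, exact = TRUE)
  # within ranks {1.5, 1.5}, between {3, 4.5, 4.5, 6}: R = (4.5 - 1.5)/3
  expect_identical(res$R, 1)
  expect_equal(res$p, 1 / 3)
  expect_identical(res$nPerm, 3L)
})

test_that("ANOSIM is ~0 for identical groups and bounded in [-1, 1]", {
  x <- matrix(rep(c(1, 2, 3, 4), 2), ncol = 1)
  res <- anosimTest(x, rep(c("a", "b"), each = 4), nPerm = 99)
  expect_lt(abs(res$R), 0.3)
  set.seed(42)
  for (i in 1:5) {
    y <- matrix(rnorm(40), 10)
    r <- anosimTest(y, rep(1:2, 5), nPerm = 19, seed = i)
    expect_true(r$R >= -1 && r$R <= 1)
    expect_true(all(r$permR >= -1 & r$permR <= 1))
  }
})

test_that("ANOSIM agrees with the vegan implementation", {
  skip_if_not_installed("vegan")
  set.seed(9)
  x <- matrix(rnorm(60), 12)
  x[7:12, 1:2] <- x[7:12, 1:2] + 1.5
  g <- rep(c("a", "b"), each = 6)
  ours <- anosimTest(x, g, nPerm = 99)
  ref <- vegan::anosim(dist(x), g, permutations = 99)
  expect_equal(ours$R, unname(ref$statistic), tolerance = 1e-12)
})

test_that("ANOSIM p-values are uniform under the null", {
  set.seed(123)
  ps <- replicate(200, {
    x <- matrix(rnorm(16 * 3), 16)
    anosimTest(x, rep(1:2, each = 8),
      nPerm = 49,
      seed = sample.int(1e6, 1)
    )$p
  })
  # attainable p-values are i/50; compare against the discrete uniform
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_gt(mean(ps), 0.4)
  expect_lt(mean(ps), 0.6)
})

test_that("ANOSIM finds p = 0.001 for strongly separated groups", {
  set.seed(1)
  x <- rbind(
    matrix(rnorm(20 * 10), 20),
    matrix(rnorm(20 * 10, mean = 4), 20)
  )
  res <- anosimTest(x, rep(c("a", "b"), each = 20), nPerm = 999, seed = 1)
  expect_equal(res$p, 0.001)
  expect_true(all(res$permR < res$R))
})

test_that("SDM follows its closed form and ignores replicate order", {
  base <- tinyRamanome(n = 4, b = 30, state = "preprocessed")
  expect_equal(sdmReproducibility(list(base, base))$sdmMean, 0)

  m <- scrs(base)
  delta <- 0.01
  shifted <- Ramanome(m + delta, wavenumbers(base), cellData(base),
    processingState = "raw"
  )
  # bypass state validity: SDM works on any shared-grid collection
  r1 <- sdmReproducibility(list(base, shifted))
  expect_equal(r1$sdmMean, delta / sqrt(2), tolerance = 1e-10)
  expect_equal(r1$sdmSd, 0, tolerance = 1e-10)
  r2 <- sdmReproducibility(list(shifted, base))
  expect_equal(r2$sdmMean, r1$sdmMean)

  expect_error(sdmReproducibility(list(base)), ">= 2")
})

test_that("band tests reproduce the exact Wilcoxon enumeration", {
  grid <- seq(640, 1800, length.out = 5)
  mS <- matrix(10:12, 3, 5) + outer(rep(0, 3), 0:4)
  mC <- matrix(1:3, 3, 5) + outer(rep(0, 3), 0:4)
  s <- asPreprocessed(mS, grid)
  c0 <- asPreprocessed(mC, grid)
  # build un-normalized variants through direct construction
  sr <- Ramanome(mS, grid, cellData(s), processingState = "raw")
  cr <- Ramanome(mC, grid, cellData(c0), processingState = "raw")
  bt <- bandTests(sr, cr, alpha = 0.2, adjust = "none")
  # {10,11,12} vs {1,2,3}: two-sided exact p = 2 * 1/C(6,3) * ... = 0.1
  expect_equal(bt$p_raw, rep(0.1, 5))
  expect_equal(bt$d_value, rep(9, 5))
  expect_identical(bt$sign, rep(1, 5))

  flipped <- bandTests(cr, sr, alpha = 0.2, adjust = "none")
  expect_equal(flipped$d_value, -bt$d_value)
  expect_equal(flipped$p_raw, bt$p_raw)
})

test_that("identical groups give zero D-values and no sign calls", {
  r <- tinyRamanome(n = 5, b = 20, gain = c(1, 1.2, 0.9, 1.1, 1), state = "preprocessed")
  bt <- bandTests(r, r)
  expect_equal(bt$d_value, rep(0, nrow(bt)))
  expect_identical(unique(bt$sign), 0)
})

test_that("BH adjustment preserves the raw p ordering", {
  set.seed(8)
  a <- asPreprocessed(matrix(abs(rnorm(10 * 30, 5)), 10))
  b <- asPreprocessed(matrix(abs(rnorm(10 * 30, 5.5)), 10))
  bt <- bandTests(a, b, adjust = "bh")
  o <- order(bt$p_raw)
  expect_true(all(diff(bt$p_adj[o]) >= -1e-12))
  expect_true(all(bt$p_adj >= bt$p_raw - 1e-12))
})

test_that("Kruskal-Wallis matches the rank formula and the two-group rank-sum", {
  g <- list(c(1, 2, 3), c(10, 11, 12), c(20, 21, 22))
  res <- kruskalCompare(g)
  # untied brute force: H = 12/(N(N+1)) * sum n_i (rbar_i - rbar)^2
  rk <- rank(unlist(g))
  n <- lengths(g)
  rb <- tapply(rk, rep(seq_along(g), n), mean)
  H <- 12 / (9 * 10) * sum(n * (rb - mean(rk))^2)
  expect_equal(res$H, H)
  expect_equal(res$df, 2)

  set.seed(3)
  x <- rnorm(60)
  y <- rnorm(60, 0.8)
  kw <- kruskalCompare(list(x, y))
  wt <- wilcox.test(x, y, exact = FALSE, correct = FALSE)
  z <- qnorm(wt$p.value / 2, lower.tail = FALSE)
  expect_equal(kw$H, z^2, tolerance = 0.01)
  expect_error(kruskalCompare(list(x)), ">= 2")
})
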