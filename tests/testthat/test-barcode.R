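mkMarkers <- function(bands, importance = rev(seq_along(bands))) {
  out <- data.frame(
    wavenumber = bands, importance = importance,
    sign = 1, category = NA_character_
  )
  out[order(-out$importance, out$wavenumber), ]
}

mkSigns <- function(bands, times, markerBands, sign = 1) {
  lapply(seq_along(times), function(j) {
    data.frame(
      wavenumber = bands,
      d_value = 0, p_raw = 1, p_adj = 1,
      sign = ifelse(bands %in% markerBands & times[j] > 0, sign, 0)
    )
  })
}

test_that("RBCS pools markers with the expected union arithmetic", {
  grid <- seq(650, 1750, by = 10)
  times <- c(0, 30, 60)
  bandsA <- grid[seq(1, 19, by = 2)] # 10 bands
  bandsB <- grid[seq(40, 62, by = 2)] # 12 bands, disjoint
  ms <- list(A = mkMarkers(bandsA), B = mkMarkers(bandsB))
  sc <- list(
    A = mkSigns(grid, times, bandsA, 1),
    B = mkSigns(grid, times, bandsB, -1)
  )
  rb <- buildRBCS(ms, sc, times, targetSize = 31)
  expect_identical(length(rb@bands), 22L)
  expect_identical(sum(rb@sharing$class == "all_shared"), 0L)
  expect_setequal(rb@sharing$class, "specific")
  # entries zero at t = 0, signed elsewhere
  expect_true(all(rb@signs$A[, 1] == 0))
  expect_true(all(rb@signs$A[rb@bands %in% bandsA, -1] == 1))
  expect_true(all(rb@signs$B[rb@bands %in% bandsA, ] == 0))

  # identical marker sets: every band is all-shared
  ms2 <- list(A = mkMarkers(bandsA), B = mkMarkers(bandsA))
  sc2 <- list(A = sc$A, B = mkSigns(grid, times, bandsA, -1))
  rb2 <- buildRBCS(ms2, sc2, times)
  expect_setequal(rb2@sharing$class, "all_shared")

  # stressor input order does not change the barcode (up to row order)
  rb3 <- buildRBCS(ms[c("B", "A")], sc[c("B", "A")], times, targetSize = 31)
  expect_identical(rb3@bands, rb@bands)
  expect_identical(rb3@signs$A, rb@signs$A)
})

test_that("capping keeps the highest summed importance with spacing", {
  grid <- seq(650, 1750, by = 10)
  times <- c(0, 30)
  bands <- grid[1:40]
  imp <- 40:1
  ms <- list(A = mkMarkers(bands, imp), B = mkMarkers(bands, imp))
  sc <- list(A = mkSigns(grid, times, bands), B = mkSigns(grid, times, bands))
  rb <- buildRBCS(ms, sc, times, targetSize = 31, minSeparation = 10)
  expect_identical(length(rb@bands), 31L)
  expect_true(all(rb@bands == sort(bands[1:31]))) # highest-importance prefix
  expect_true(all(diff(rb@bands) >= 10))
})

test_that("sharing analysis reproduces the reference set geometry", {
  # reference geometry as sets: 6 bands shared by all six stressors,
  # 26 of 31 shared between the two metals, 18 between the two alcohols
  all6 <- c(666, 811, 1575, 853, 1302, 957)
  pool <- c(
    all6, 620, 720, 728, 782, 823, 1002, 1092, 1127, 1242, 1308,
    1445, 1448, 1481, 1620, 1658, 1661, 1046, 1380, 645, 678, 760, 830, 898, 937
  )[1:31]
  eth <- c(all6, setdiff(pool, all6)[1:18])
  nbut <- c(all6, setdiff(pool, all6)[7:18]) # 18 bands shared with Eth
  cu <- c(all6, setdiff(pool, all6)[1:22])
  cr <- c(all6, setdiff(pool, all6)[3:22]) # 26 shared with Cu
  amp <- c(all6, setdiff(pool, all6)[20:25])
  kan <- c(all6, setdiff(pool, all6)[23:25])
  sets <- list(Eth = eth, nBut = nbut, Amp = amp, Kan = kan, Cu = cu, Cr = cr)
  sh <- sharingAnalysis(sets, groups = c(
    Eth = "alcohol", nBut = "alcohol",
    Amp = "antibiotic", Kan = "antibiotic", Cu = "metal", Cr = "metal"
  ))
  expect_identical(length(sh$allShared), 6L)
  pw <- sh$pairwise
  expect_identical(pw$shared[pw$a == "Cu" & pw$b == "Cr"], 26L)
  expect_identical(pw$shared[pw$a == "Eth" & pw$b == "nBut"], 18L)
  # symmetry
  sh2 <- sharingAnalysis(sets[c(6:1)])
  pw2 <- sh2$pairwise
  expect_identical(
    pw2$shared[(pw2$a == "Cr" & pw2$b == "Cu") | (pw2$a == "Cu" & pw2$b == "Cr")],
    26L
  )
  # disjoint sets overlap in nothing
  dj <- sharingAnalysis(list(A = c(700, 800), B = c(900, 1000)))
  expect_identical(dj$pairwise$shared, 0L)
  expect_identical(length(dj$allShared), 0L)
})

test_that("barcode clustering merges identical stressors first", {
  grid <- seq(650, 1750, by = 10)
  times <- c(0, 30)
  bandsA <- grid[1:10]
  bandsB <- grid[30:39]
  ms <- list(
    X = mkMarkers(bandsA), Y = mkMarkers(bandsA),
    Z = mkMarkers(bandsB)
  )
  sc <- list(
    X = mkSigns(grid, times, bandsA, 1),
    Y = mkSigns(grid, times, bandsA, 1),
    Z = mkSigns(grid, times, bandsB, -1)
  )
  rb <- buildRBCS(ms, sc, times)
  dg <- clusterRBCS(rb)
  m <- as.matrix(dg$dist)
  expect_equal(unname(diag(m)), rep(0, 3))
  expect_equal(m, t(m))
  expect_equal(m["X", "Y"], 0)
  expect_gt(m["X", "Z"], 0)
  expect_identical(dg$hclust$merge[1, ], c(-1L, -2L)) # X and Y merge first
  expect_match(dg$newick, "X.*Y|Y.*X")
})

test_that("planted two-family signatures are recovered as monophyletic clades", {
  hits <- 0L
  nSeeds <- 5L
  for (seed in seq_len(nSeeds)) {
    d <- twoFamilyDesign(seed)
    pp <- preprocessRamanome(simulateRamanome(d)$ramanome)
    times <- sort(unique(cellData(pp)$time_min))
    chains <- lapply(setNames(names(d$signatures), names(d$signatures)), function(s) {
      markerChain(pp, s, times)
    })
    rb <- buildRBCS(
      lapply(chains, `[[`, "markers"),
      lapply(chains, `[[`, "tests"), times
    )
    dg <- clusterRBCS(rb)
    m <- as.matrix(dg$dist)
    within <- c(m["A1", "A2"], m["B1", "B2"])
    between <- c(m["A1", "B1"], m["A1", "B2"], m["A2", "B1"], m["A2", "B2"])
    if (max(within) < min(between)) hits <- hits + 1L
  }
  expect_gte(hits, nSeeds - 1L)
})
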