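# shared fixtures: small constructed ramanomes and cached scenario runs

.tinyGrid <- function(n = 25L) seq(600, 1800, length.out = n)

# cells x bands matrix with a constant spectral shape, optional per-cell gain
tinyRamanome <- function(n = 4L, b = 25L, gain = rep(1, n), state = "raw",
                         stressor = "none", dose = 0, time = 0, replicate = 1) {
  grid <- .tinyGrid(b)
  shape <- 1 + exp(-(grid - 1000)^2 / (2 * 30^2))
  m <- outer(gain, shape)
  if (state == "preprocessed") m <- m / sqrt(rowSums(m^2))
  cells <- data.frame(
    cell_id = sprintf("c%02d", seq_len(n)), stressor = stressor,
    dose = dose, dose_unit = "", time_min = time,
    replicate = rep_len(replicate, n)
  )
  Ramanome(m, grid, cells, processingState = state)
}

# wrap a plain matrix (cells x bands) as a preprocessed Ramanome
asPreprocessed <- function(m, grid = NULL, replicate = 1) {
  if (is.null(grid)) grid <- .tinyGrid(ncol(m))
  m <- m / sqrt(rowSums(m^2))
  cells <- data.frame(
    cell_id = sprintf("c%03d", seq_len(nrow(m))), stressor = "none",
    dose = 0, dose_unit = "", time_min = 0,
    replicate = rep_len(replicate, nrow(m))
  )
  Ramanome(m, grid, cells, processingState = "preprocessed")
}

# cache expensive simulated scenarios across test files (one process)
.scenarioCache <- new.env(parent = emptyenv())
cachedPreprocessed <- function(name, seed = 1L) {
  key <- paste(name, seed, sep = "_")
  if (is.null(.scenarioCache[[key]])) {
    sim <- simulateRamanome(scenarioLibrary(name, seed = seed))
    .scenarioCache[[key]] <- list(
      pp = preprocessRamanome(sim$ramanome),
      groundTruth = sim$groundTruth
    )
  }
  .scenarioCache[[key]]
}

# six_stressors is large: preprocess only the requested time slice
cachedSixSlice <- function(timeMin = 60, seed = 1L) {
  key <- paste("six", timeMin, seed, sep = "_")
  if (is.null(.scenarioCache[[key]])) {
    sim <- simulateRamanome(scenarioLibrary("six_stressors", seed = seed))
    cd <- cellData(sim$ramanome)
    .scenarioCache[[key]] <- preprocessRamanome(
      sim$ramanome[, cd$time_min == timeMin]
    )
  }
  .scenarioCache[[key]]
}

# small planted two-family design (alcohol-like vs metal-like) on a coarse
# grid, for dendrogram-recovery properties
twoFamilyDesign <- function(seed) {
  mk <- function(label, eff, tpl) {
    stressorSignature(label, eff, template = tpl, doseRef = 1)
  }
  famA <- c(nucleic_acid = -2.5, protein = 3.5, lipid = 4.0, carbohydrate = 2.8)
  famB <- c(nucleic_acid = 3.0, protein = -3.0, lipid = -2.5, carbohydrate = 1.8)
  sigs <- list(
    A1 = mk("A1", famA, "linear_updown"),
    A2 = mk("A2", famA * 0.85, "updown_late"),
    B1 = mk("B1", famB, "down_up"),
    B2 = mk("B2", famB * 0.85, "complex_b")
  )
  simDesign(sigs,
    doses = 1, timesMin = c(30, 60, 180), includeControl = TRUE,
    cellsPerCondition = 10L, replicates = 2L,
    grid = seq(600, 1800, length.out = 400L), seed = seed
  )
}

# run the marker chain for one stressor of a preprocessed ramanome
markerChain <- function(pp, stressor, times, alpha = 0.001) {
  cd <- cellData(pp)
  sl <- lapply(times, function(t) pp[, cd$stressor == stressor & cd$time_min == t])
  cl <- lapply(times, function(t) pp[, cd$stressor == "none" & cd$time_min == t])
  prof <- dValueProfiles(sl, cl, times, stressor = stressor)
  tests <- lapply(seq_along(times), function(j) {
    bandTests(sl[[j]], cl[[j]], alpha = alpha)
  })
  list(profile = prof, tests = tests,
       markers = significantBands(prof, tests))
}

# direct silhouette computation from the textbook formula, for tiny inputs
bruteSilhouette <- function(x, cl) {
  d <- as.matrix(dist(x))
  mean(vapply(seq_len(nrow(x)), function(i) {
    own <- cl == cl[i]
    a <- if (sum(own) > 1) mean(d[i, own & seq_len(nrow(x)) != i]) else 0
    b <- min(vapply(setdiff(unique(cl), cl[i]), function(k) {
      mean(d[i, cl == k])
    }, numeric(1)))
    if (sum(own) > 1) (b - a) / max(a, b) else 0
  }, numeric(1)))
}

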