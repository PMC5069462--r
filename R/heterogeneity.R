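#' Per-band inter-cellular heterogeneity (RSD) profile
#'
#' The relative standard deviation (sample SD divided by mean) of each
#' band's normalized intensity across the cells of a ramanome quantifies
#' the inter-cellular phenotypic heterogeneity of the population.  Bands
#' whose absolute mean falls below `meanFloor` are flagged `undefined` and
#' their RSD set to `NA`.
#'
#' @param r a preprocessed [Ramanome-class] with >= 3 cells
#' @param meanFloor minimal |mean| for a defined RSD (default 1e-6,
#'   normalized units)
#' @param fingerprint wavenumber range
#' @return `data.frame` of class `"RsdProfile"`: `wavenumber`, `mean`,
#'   `sd`, `rsd`, `undefined`; attribute `n` holds the cell count
#' @export
rsdProfile <- function(r, meanFloor = 1e-6, fingerprint = c(640, 1800)) {
  stopifnot(is(r, "Ramanome"))
  if (processingState(r) != "preprocessed") stop("ramanome must be preprocessed")
  if (ncol(r) < 3L) stop("need >= 3 cells")
  r <- cropSpectra(r, fingerprint[1], fingerprint[2])
  x <- scrs(r)
  mu <- colMeans(x)
  sd_ <- apply(x, 2L, stats::sd)
  undef <- abs(mu) < meanFloor
  out <- data.frame(
    wavenumber = wavenumbers(r), mean = mu, sd = sd_,
    rsd = ifelse(undef, NA_real_, sd_ / mu), undefined = undef
  )
  attr(out, "n") <- ncol(r)
  class(out) <- c("RsdProfile", "data.frame")
  out
}

#' Compare inter-cellular heterogeneity at one band across conditions
#'
#' Kruskal-Wallis test on replicate-level RSD values at the band nearest to
#' `band` (within the annotation tolerance).  Using biological replicates
#' (not cells) as the test units avoids pseudo-replication; as an
#' alternative, `perCellBootstrap` resamples cells within each replicate to
#' produce the replicate-level values.
#'
#' @param profiles named list (one per condition) of lists of
#'   [rsdProfile()] results, one per biological replicate (>= 2 each)
#' @param band nominal wavenumber (cm^-1)
#' @param alpha significance level (default 0.05)
#' @param tolerance band-matching tolerance (cm^-1)
#' @return list: `band`, `matched`, `H`, `p`, `significant`, `values`
#'   (per-condition replicate RSDs)
#' @export
heterogeneityCompare <- function(profiles, band, alpha = 0.05, tolerance = 4) {
  if (length(profiles) < 2L) stop("need >= 2 conditions")
  if (any(lengths(profiles) < 2L)) stop("each condition needs >= 2 replicate profiles")
  grid <- profiles[[1]][[1]]$wavenumber
  i <- matchBands(grid, band, tolerance)
  vals <- lapply(profiles, function(reps) {
    vapply(reps, function(p) p$rsd[i], numeric(1))
  })
  if (anyNA(unlist(vals))) stop("RSD undefined at the requested band")
  kt <- kruskalCompare(vals, alpha = alpha)
  c(list(band = band, matched = grid[i], values = vals), kt)
}
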