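#' Temporal D-value profiles of a stressed/control time series
#'
#' For each fingerprint band and time point, the D-value is the mean
#' normalized intensity of the stressed cells minus the mean of the matched
#' control cells.  The column at time 0 is defined as zero (no effect at
#' stress onset).
#'
#' @param stressed,control lists of preprocessed [Ramanome-class] objects,
#'   one pair per time point, on a shared grid
#' @param times time axis in minutes, same length as the lists
#' @param stressor stressor label carried in the result
#' @param fingerprint wavenumber range
#' @return list of class `"DValueProfile"`: `d` (bands x times matrix),
#'   `times`, `wavenumber`, `stressor`
#' @export
dValueProfiles <- function(stressed, control, times, stressor = "stress",
                           fingerprint = c(640, 1800)) {
  if (length(stressed) != length(times) || length(control) != length(times)) {
    stop("need one stressed and one control ramanome per time point")
  }
  cols <- lapply(seq_along(times), function(i) {
    if (times[i] == 0) {
      s <- cropSpectra(stressed[[i]], fingerprint[1], fingerprint[2])
      return(numeric(nrow(s)))
    }
    s <- cropSpectra(stressed[[i]], fingerprint[1], fingerprint[2])
    c0 <- cropSpectra(control[[i]], fingerprint[1], fingerprint[2])
    if (!identical(wavenumbers(s), wavenumbers(c0))) stop("grid mismatch at t=", times[i])
    colMeans(scrs(s)) - colMeans(scrs(c0))
  })
  d <- do.call(cbind, cols)
  wn <- wavenumbers(cropSpectra(stressed[[1]], fingerprint[1], fingerprint[2]))
  dimnames(d) <- list(NULL, paste0("t", times))
  structure(
    list(d = d, times = times, wavenumber = wn, stressor = stressor),
    class = "DValueProfile"
  )
}

#' Select stress-responsive marker bands from a temporal profile
#'
#' A band is kept when its sign call (from the per-time [bandTests()]
#' results) is nonzero at >= `minTimes` of the time points; its importance
#' is the largest absolute D-value over time, and its sign the majority
#' nonzero sign.  Bands are returned ordered by descending importance (ties
#' toward the lower wavenumber).
#'
#' @param profile a [dValueProfiles()] result
#' @param tests list of [bandTests()] results aligned with the nonzero time
#'   points of `profile` (named by time, or in matching order)
#' @param minTimes persistence rule (default 2 time points)
#' @param annotation optional [BandAnnotation-class] for band categories
#' @return `data.frame` of class `"MarkerBandSet"`: `wavenumber`,
#'   `importance`, `sign`, `category`; empty (with a warning) when nothing
#'   is significant
#' @export
significantBands <- function(profile, tests, minTimes = 2L, annotation = NULL) {
  stopifnot(inherits(profile, "DValueProfile"))
  signs <- vapply(tests, function(tt) {
    if (!isTRUE(all.equal(tt$wavenumber, profile$wavenumber))) {
      stop("tests are not aligned with the profile grid")
    }
    tt$sign
  }, numeric(length(profile$wavenumber)))
  nSig <- rowSums(signs != 0)
  keep <- which(nSig >= minTimes)
  if (!length(keep)) {
    warning("no band is significant at >= ", minTimes, " time points")
    out <- data.frame(
      wavenumber = numeric(), importance = numeric(),
      sign = numeric(), category = character()
    )
    class(out) <- c("MarkerBandSet", "data.frame")
    return(out)
  }
  importance <- apply(abs(profile$d[keep, , drop = FALSE]), 1L, max)
  majSign <- apply(signs[keep, , drop = FALSE], 1L, function(s) {
    s <- s[s != 0]
    if (sum(s > 0) >= sum(s < 0)) 1 else -1
  })
  wn <- profile$wavenumber[keep]
  cat_ <- if (is.null(annotation)) {
    rep(NA_character_, length(wn))
  } else {
    annotateBand(annotation, wn)$category
  }
  ord <- order(-importance, wn)
  out <- data.frame(
    wavenumber = wn, importance = importance,
    sign = majSign, category = cat_
  )[ord, ]
  rownames(out) <- NULL
  class(out) <- c("MarkerBandSet", "data.frame")
  out
}

#' Silhouette width of a clustering (mean over points)
#'
#' @param d a [stats::dist]
#' @param clusterIds integer cluster assignment
#' @return mean silhouette width
#' @keywords internal
.meanSilhouette <- function(d, clusterIds) {
  mean(cluster::silhouette(clusterIds, d)[, "sil_width"])
}

#' Cluster temporal D-value profiles of marker bands
#'
#' Rows (bands) are standardized to zero mean and unit variance over time
#' (shape clustering: magnitude is already captured by the marker
#' importances), then clustered by K-means with Euclidean distance and >= 10
#' restarts per candidate `k`; the `k` with the largest mean silhouette
#' coefficient is selected.
#'
#' @param profile a [dValueProfiles()] result
#' @param bands wavenumbers of the marker bands to cluster (default all
#'   rows of the profile)
#' @param kRange candidate cluster counts, a subset of 2..6 (default 2:4)
#' @param nstart K-means restarts (default 10)
#' @param seed RNG seed
#' @param annotation optional [BandAnnotation-class] for per-cluster
#'   category composition
#' @return list of class `"TemporalClusters"`: `cluster` (per band), `k`,
#'   `silhouette`, `bands`, `centers`, `composition`
#' @export
clusterTemporal <- function(profile, bands = NULL, kRange = 2:4, nstart = 10L,
                            seed = 1L, annotation = NULL) {
  stopifnot(inherits(profile, "DValueProfile"))
  if (!all(kRange %in% 2:6)) stop("kRange must lie within 2..6")
  d <- profile$d
  wn <- profile$wavenumber
  if (!is.null(bands)) {
    i <- matchBands(wn, bands)
    d <- d[i, , drop = FALSE]
    wn <- wn[i]
  }
  if (nrow(d) < 4L) stop("need >= 4 bands to cluster")
  if (nrow(d) <= max(kRange)) stop("fewer bands than the largest k")
  rsd <- apply(d, 1L, stats::sd)
  if (all(rsd < 1e-12)) stop("no temporal structure: all profiles are identical")
  z <- (d - rowMeans(d)) / pmax(rsd, 1e-12)
  z[rsd < 1e-12, ] <- 0
  dd <- stats::dist(z)
  if (max(dd) < 1e-10) stop("no temporal structure: all profiles are identical")
  set.seed(seed)
  fits <- lapply(kRange, function(k) stats::kmeans(z, centers = k, nstart = nstart))
  sil <- vapply(seq_along(kRange), function(i) .meanSilhouette(dd, fits[[i]]$cluster), numeric(1))
  best <- which.max(sil)
  fit <- fits[[best]]
  comp <- NULL
  if (!is.null(annotation)) {
    cats <- annotateBand(annotation, wn)$category
    comp <- as.data.frame.matrix(proportions(table(fit$cluster, cats), margin = 1L))
  }
  structure(
    list(
      cluster = stats::setNames(fit$cluster, wn), k = kRange[best],
      silhouette = sil[best], silhouetteByK = stats::setNames(sil, kRange),
      bands = wn, centers = fit$centers, composition = comp
    ),
    class = "TemporalClusters"
  )
}

#' @export
print.TemporalClusters <- function(x, ...) {
  cat(sprintf(
    "Temporal K-means clustering: k = %d (mean silhouette %.3f) over %d bands\n",
    x$k, x$silhouette, length(x$bands)
  ))
  print(table(cluster = x$cluster))
  invisible(x)
}
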