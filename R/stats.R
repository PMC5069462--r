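#' Permutation analysis of similarities (ANOSIM)
#'
#' Rank-based test of whether between-group dissimilarities exceed
#' within-group dissimilarities.  With average ranks `r` of all pairwise
#' distances, `R = (mean(r_between) - mean(r_within)) / (M/2)` where
#' `M = n(n-1)/2`; `R` lies in [-1, 1] and equals 1 exactly when every
#' between-group distance outranks every within-group distance.  The p-value
#' is obtained by label permutation:
#' `p = (1 + #\{permuted R >= observed R\}) / (nPerm + 1)`, or by exhaustive
#' enumeration of the distinct two-group label partitions when
#' `exact = TRUE`.
#'
#' @param x a preprocessed [Ramanome-class] (its fingerprint region is
#'   used), a numeric matrix of observations in rows, or a [stats::dist]
#' @param labels group label per observation (>= 2 groups of >= 2)
#' @param nPerm number of permutations (default 999, so the smallest
#'   attainable p is 0.001)
#' @param metric `"euclidean"` or `"cosine"` (ignored for a `dist` input)
#' @param seed RNG seed for the permutations
#' @param exact enumerate all distinct label partitions (two groups only)
#' @param fingerprint wavenumber range used when `x` is a `Ramanome`
#' @return list of class `"AnosimResult"`: `R`, `p`, `nPerm`, `metric`,
#'   `permR` (the permuted statistics)
#' @examples
#' anosimTest(matrix(c(0, 1, 10, 11)), c("a", "a", "b", "b"), exact = TRUE)
#' @export
anosimTest <- function(x, labels, nPerm = 999L, metric = c("euclidean", "cosine"),
                       seed = 1L, exact = FALSE, fingerprint = c(640, 1800)) {
  metric <- match.arg(metric)
  d <- .toDist(x, metric, fingerprint)
  labels <- as.factor(labels)
  n <- attr(d, "Size")
  if (length(labels) != n) stop("labels length must match the number of observations")
  tab <- table(labels)
  if (length(tab) < 2L || any(tab < 2L)) stop("need >= 2 groups with >= 2 members each")
  rk <- rank(as.numeric(d)) # average ranks for ties
  M <- n * (n - 1) / 2
  stat <- function(lab) {
    within <- .withinMask(lab)
    (mean(rk[!within]) - mean(rk[within])) / (M / 2)
  }
  Robs <- stat(labels)
  if (exact) {
    if (length(tab) != 2L) stop("exact enumeration implemented for two groups")
    n1 <- tab[1L]
    combs <- utils::combn(n, n1)
    permR <- apply(combs, 2L, function(i) {
      lab <- factor(ifelse(seq_len(n) %in% i, "g1", "g2"))
      stat(lab)
    })
    p <- mean(permR >= Robs - 1e-12)
    # each distinct partition appears twice when the group sizes are equal,
    # which leaves the proportion (and hence p) unchanged
    nPerm <- if (tab[1L] == tab[2L]) ncol(combs) %/% 2L else ncol(combs)
  } else {
    if (nPerm < 1L) stop("nPerm must be >= 1")
    set.seed(seed)
    permR <- vapply(seq_len(nPerm), function(i) stat(sample(labels)), numeric(1))
    p <- (1 + sum(permR >= Robs - 1e-12)) / (nPerm + 1)
  }
  structure(
    list(R = Robs, p = p, nPerm = nPerm, metric = metric, permR = permR),
    class = "AnosimResult"
  )
}

.withinMask <- function(labels) {
  g <- as.integer(labels)
  n <- length(g)
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- sequence((n - 1L):1L, from = 2:n)
  g[i] == g[j]
}

.toDist <- function(x, metric, fingerprint) {
  if (inherits(x, "dist")) {
    return(x)
  }
  if (is(x, "Ramanome")) {
    x <- scrs(cropSpectra(x, fingerprint[1], fingerprint[2]))
  }
  x <- as.matrix(x)
  if (metric == "euclidean") {
    stats::dist(x)
  } else {
    nx <- x / sqrt(rowSums(x^2))
    stats::as.dist(1 - tcrossprod(nx))
  }
}

#' @export
print.AnosimResult <- function(x, ...) {
  cat(sprintf(
    "ANOSIM: R = %.4f, p = %.4g (%d permutations, %s distance)\n",
    x$R, x$p, x$nPerm, x$metric
  ))
  invisible(x)
}

#' Standard deviation of the mean across biological replicates
#'
#' Reproducibility metric of a ramanome measurement: compute each
#' replicate's mean spectrum, then the per-band sample SD across those
#' replicate means; report the average (`sdmMean`) and SD (`sdmSd`) of the
#' per-band SDs over the fingerprint bands.
#'
#' @param replicates list of preprocessed [Ramanome-class] objects on one
#'   grid (one per biological replicate), or a single `Ramanome` that is
#'   split by its `replicate` metadata column
#' @param fingerprint wavenumber range
#' @return list of class `"SdmResult"`: `sdmMean`, `sdmSd`, `nReplicates`,
#'   `perBand`
#' @export
sdmReproducibility <- function(replicates, fingerprint = c(640, 1800)) {
  if (is(replicates, "Ramanome")) {
    replicates <- splitRamanome(replicates, "replicate")
  }
  if (length(replicates) < 2L) stop("need >= 2 replicates")
  grids <- lapply(replicates, wavenumbers)
  if (!all(vapply(grids[-1], identical, logical(1), grids[[1]]))) {
    stop("replicate grids differ")
  }
  means <- vapply(
    replicates,
    function(r) colMeans(scrs(cropSpectra(r, fingerprint[1], fingerprint[2]))),
    numeric(sum(grids[[1]] >= fingerprint[1] & grids[[1]] <= fingerprint[2]))
  )
  perBand <- apply(means, 1L, stats::sd)
  structure(
    list(
      sdmMean = mean(perBand), sdmSd = stats::sd(perBand),
      nReplicates = length(replicates), perBand = perBand
    ),
    class = "SdmResult"
  )
}

#' @export
print.SdmResult <- function(x, ...) {
  cat(sprintf(
    "SDM over %d replicates: %.4g +/- %.4g\n",
    x$nReplicates, x$sdmMean, x$sdmSd
  ))
  invisible(x)
}

#' Split a ramanome by a metadata column
#'
#' @param r a [Ramanome-class]
#' @param by metadata column name (e.g. `"replicate"`, `"stressor"`)
#' @return named list of `Ramanome` objects
#' @export
splitRamanome <- function(r, by) {
  f <- cellData(r)[[by]]
  if (is.null(f)) stop("no metadata column '", by, "'")
  lapply(split(seq_len(ncol(r)), f), function(i) r[, i])
}

#' Per-band stressed-versus-control tests with D-values
#'
#' For every fingerprint band, the D-value is the mean normalized intensity
#' of the stressed cells minus that of the control cells; a two-sided
#' Wilcoxon rank-sum test (exact when the combined sample size is <= 20 and
#' untied, normal approximation with tie correction otherwise) gives the
#' p-value, adjusted across bands by Benjamini-Hochberg.  The per-band sign
#' is `sgn(D)` where the adjusted p is below `alpha`, else 0.
#'
#' @param stressed,control preprocessed [Ramanome-class] objects on one
#'   grid, each with >= 3 cells
#' @param alpha significance level for the sign call (default 0.001)
#' @param adjust `"bh"` (default) or `"none"`
#' @param fingerprint wavenumber range tested
#' @return `data.frame` of class `"BandTestResult"`: `wavenumber`,
#'   `d_value`, `p_raw`, `p_adj`, `sign`
#' @export
bandTests <- function(stressed, control, alpha = 0.001,
                      adjust = c("bh", "none"), fingerprint = c(640, 1800)) {
  adjust <- match.arg(adjust)
  stressed <- cropSpectra(stressed, fingerprint[1], fingerprint[2])
  control <- cropSpectra(control, fingerprint[1], fingerprint[2])
  if (!identical(wavenumbers(stressed), wavenumbers(control))) {
    stop("stressed and control grids differ")
  }
  xs <- scrs(stressed)
  xc <- scrs(control)
  if (nrow(xs) < 3L || nrow(xc) < 3L) stop("each group needs >= 3 cells")
  useExact <- (nrow(xs) + nrow(xc)) <= 20L
  pRaw <- vapply(seq_len(ncol(xs)), function(b) {
    suppressWarnings(stats::wilcox.test(xs[, b], xc[, b],
      exact = useExact, correct = TRUE
    ))$p.value
  }, numeric(1))
  pRaw[is.na(pRaw)] <- 1 # fully tied band: no evidence either way
  d <- colMeans(xs) - colMeans(xc)
  pAdj <- if (adjust == "bh") stats::p.adjust(pRaw, "BH") else pRaw
  sgn <- ifelse(pAdj < alpha, sign(d), 0)
  structure(
    data.frame(
      wavenumber = wavenumbers(stressed), d_value = d,
      p_raw = pRaw, p_adj = pAdj, sign = sgn
    ),
    class = c("BandTestResult", "data.frame"), alpha = alpha
  )
}

#' Kruskal-Wallis comparison of per-cell scalar samples
#'
#' @param samples list (>= 2) of numeric vectors, one per group
#' @param alpha significance level for the flag (default 0.05)
#' @return list: `H`, `p`, `df`, `significant`
#' @export
kruskalCompare <- function(samples, alpha = 0.05) {
  if (length(samples) < 2L || any(lengths(samples) < 2L)) {
    stop("need >= 2 groups with >= 2 values each")
  }
  kt <- stats::kruskal.test(samples)
  list(
    H = unname(kt$statistic), p = kt$p.value,
    df = unname(kt$parameter), significant = kt$p.value < alpha
  )
}
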