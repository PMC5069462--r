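#' Preprocessing configuration
#'
#' Parameters controlling the raw-to-comparable SCRS pipeline: cropping to
#' the measured 600-1800 cm^-1 range, asymmetric-least-squares baseline
#' removal, optional resampling, vector normalization and SNR-based quality
#' control.  Analysis functions additionally restrict to the fingerprint
#' region starting at `fingerprintLow`.
#'
#' @param cropLow,cropHigh crop interval in cm^-1 (closed; defaults 600, 1800).
#' @param fingerprintLow lower bound of the fingerprint region used by the
#'   analysis modules (default 640 cm^-1).
#' @param baselineLambda smoothness weight of the Whittaker smoother
#'   (default 1e5).
#' @param baselineP asymmetry weight in (0, 1) (default 0.001: points above
#'   the baseline barely pull it up).
#' @param baselineIters reweighting iterations (default 10).
#' @param normMethod `"l2"` (unit Euclidean norm, default) or `"area"`
#'   (unit sum).
#' @param qcMinSnr minimal signal-to-noise ratio; cells below it are dropped
#'   (default 3).  SNR = (max - median) corrected intensity over a robust
#'   noise estimate (1.4826 x MAD of first differences, scaled) from the
#'   near-signal-free 1750-1800 cm^-1 window.
#' @param targetGrid optional wavenumber grid to resample onto after baseline
#'   correction (e.g. the canonical 1581-point grid); `NULL` keeps the
#'   cropped native grid.
#' @return a validated list of class `"PreprocessConfig"`.
#' @export
preprocessConfig <- function(cropLow = 600, cropHigh = 1800, fingerprintLow = 640,
                             baselineLambda = 1e5, baselineP = 0.001,
                             baselineIters = 10L, normMethod = c("l2", "area"),
                             qcMinSnr = 3, targetGrid = NULL) {
  normMethod <- match.arg(normMethod)
  stopifnot(
    cropLow < cropHigh, baselineP > 0, baselineP < 1,
    baselineIters >= 1, baselineLambda > 0, qcMinSnr >= 0
  )
  structure(
    list(
      cropLow = cropLow, cropHigh = cropHigh, fingerprintLow = fingerprintLow,
      baselineLambda = baselineLambda, baselineP = baselineP,
      baselineIters = as.integer(baselineIters), normMethod = normMethod,
      qcMinSnr = qcMinSnr, targetGrid = targetGrid
    ),
    class = "PreprocessConfig"
  )
}

#' Crop a ramanome to a wavenumber interval
#'
#' Keeps bands with `low <= w <= high` (closed interval).  Idempotent.
#'
#' @param r a [Ramanome-class]
#' @param low,high interval bounds in cm^-1
#' @return the cropped `Ramanome`
#' @export
cropSpectra <- function(r, low = 600, high = 1800) {
  stopifnot(is(r, "Ramanome"), low < high)
  keep <- wavenumbers(r) >= low & wavenumbers(r) <= high
  if (!any(keep)) stop("crop interval [", low, ", ", high, "] does not overlap the grid")
  r[keep, ]
}

# second-difference penalty matrix, sparse
.whittakerPenalty <- function(n, lambda) {
  D <- Matrix::bandSparse(n - 2L, n,
    k = 0:2,
    diagonals = list(rep(1, n - 2L), rep(-2, n - 2L), rep(1, n - 2L))
  )
  lambda * Matrix::crossprod(D)
}

#' Asymmetric-least-squares baseline estimation
#'
#' Estimates a smooth, non-oscillatory baseline under a spectrum with a
#' Whittaker smoother whose weights are iteratively reweighted so that
#' points above the current baseline (peaks) get weight `p` and points
#' below get `1 - p`.
#'
#' @param y numeric intensity vector (>= 16 points, all finite)
#' @param lambda smoothness penalty weight
#' @param p asymmetry weight in (0, 1)
#' @param iters reweighting iterations
#' @return list with `corrected` (y minus baseline) and `baseline`.
#' @references Eilers & Boelens (2005), baseline correction with asymmetric
#'   least squares smoothing.
#' @export
baselineALS <- function(y, lambda = 1e5, p = 0.001, iters = 10L) {
  n <- length(y)
  if (n < 16L) stop("need at least 16 bands for baseline estimation")
  if (any(!is.finite(y))) stop("non-finite intensities")
  P <- .whittakerPenalty(n, lambda)
  w <- rep(1, n)
  z <- y
  for (i in seq_len(iters)) {
    A <- P + Matrix::Diagonal(n, w)
    z <- as.numeric(Matrix::solve(A, w * y))
    w <- ifelse(y > z, p, 1 - p)
  }
  list(corrected = y - z, baseline = z)
}

#' Resample a ramanome onto a target wavenumber grid
#'
#' Linear interpolation at the target wavenumbers; the target range must lie
#' within the source range (no extrapolation).
#'
#' @param r a [Ramanome-class]
#' @param target ascending numeric grid (cm^-1)
#' @return the resampled `Ramanome`
#' @export
resampleToGrid <- function(r, target) {
  stopifnot(is(r, "Ramanome"))
  target <- as.numeric(target)
  w <- wavenumbers(r)
  if (min(target) < min(w) || max(target) > max(w)) {
    stop("target grid requires extrapolation beyond the source range")
  }
  m <- scrs(r)
  out <- t(apply(m, 1L, function(y) stats::approx(w, y, xout = target)$y))
  Ramanome(out, target, cellData(r), processingState = processingState(r))
}

#' Normalize spectra
#'
#' `"l2"` scales each spectrum to unit Euclidean norm; `"area"` clips
#' negatives to zero and scales to unit sum.
#'
#' @param r a [Ramanome-class]
#' @param method `"l2"` or `"area"`
#' @return the normalized `Ramanome` (processing state unchanged)
#' @export
normalizeSpectra <- function(r, method = c("l2", "area")) {
  method <- match.arg(method)
  m <- scrs(r)
  m2 <- .normalizeMatrix(m, method)
  Ramanome(m2, wavenumbers(r), cellData(r), processingState = processingState(r))
}

.normalizeMatrix <- function(m, method) {
  if (method == "area") m <- pmax(m, 0)
  s <- switch(method,
    l2 = sqrt(rowSums(m^2)),
    area = rowSums(m)
  )
  if (any(s == 0)) stop("cannot normalize an all-zero spectrum")
  m / s
}

#' Preprocess a raw ramanome into comparable SCRS
#'
#' Per cell: crop to `[cropLow, cropHigh]`, subtract an asymmetric-least-
#' squares baseline, optionally resample to `cfg$targetGrid`, drop cells whose
#' signal-to-noise ratio falls below `cfg$qcMinSnr`, clip residual negative
#' intensities to zero and normalize.  Dropped cells are recorded in the
#' `"dropped"` attribute of the result.
#'
#' @param r a raw [Ramanome-class]
#' @param cfg a [preprocessConfig()]
#' @return a preprocessed `Ramanome`
#' @export
preprocessRamanome <- function(r, cfg = preprocessConfig()) {
  stopifnot(is(r, "Ramanome"), inherits(cfg, "PreprocessConfig"))
  if (processingState(r) != "raw") stop("ramanome is already preprocessed")
  r <- cropSpectra(r, cfg$cropLow, cfg$cropHigh)
  w <- wavenumbers(r)
  m <- scrs(r)
  corrected <- t(apply(m, 1L, function(y) {
    baselineALS(y, cfg$baselineLambda, cfg$baselineP, cfg$baselineIters)$corrected
  }))
  # robust noise from the near-signal-free window at the top of the range;
  # first differences cancel any residual baseline left by the asymmetric
  # smoother, and the median offset is removed from the signal amplitude
  noiseIdx <- which(w >= 1750 & w <= 1800)
  if (length(noiseIdx) < 4L) noiseIdx <- utils::tail(seq_along(w), 25L)
  noise <- apply(corrected[, noiseIdx, drop = FALSE], 1L, function(v) {
    stats::mad(diff(v)) / sqrt(2)
  })
  signal <- apply(corrected, 1L, max) - apply(corrected, 1L, stats::median)
  snr <- signal / pmax(noise, .Machine$double.eps)
  keep <- snr >= cfg$qcMinSnr
  dropped <- data.frame(
    cell_id = cellData(r)$cell_id[!keep],
    snr = snr[!keep], reason = rep("snr_below_threshold", sum(!keep))
  )
  if (!any(keep)) stop("all cells failed SNR quality control")
  corrected <- corrected[keep, , drop = FALSE]
  cells <- cellData(r)[keep, , drop = FALSE]
  out <- Ramanome(corrected, w, cells, processingState = "raw")
  if (!is.null(cfg$targetGrid)) {
    out <- resampleToGrid(out, cfg$targetGrid)
  }
  m2 <- .normalizeMatrix(pmax(scrs(out), 0), cfg$normMethod)
  res <- Ramanome(m2, wavenumbers(out), cellData(out), processingState = "preprocessed")
  attr(res, "dropped") <- dropped
  res
}

#' Restrict a ramanome to the fingerprint region
#'
#' The information-rich 640-1800 cm^-1 range used by all analysis functions.
#'
#' @param r a [Ramanome-class]
#' @param low,high fingerprint bounds in cm^-1
#' @return the restricted `Ramanome`
#' @export
fingerprintRegion <- function(r, low = 640, high = 1800) {
  cropSpectra(r, low, high)
}
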