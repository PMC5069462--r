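#' Fit a NIPALS PLS1 calibration model
#'
#' Partial-least-squares regression of a per-cell scalar response (e.g.
#' latent lipid or DNA density) on the spectra, by the NIPALS algorithm for
#' a univariate response: for each component the weight is
#' `w = X'y / ||X'y||`, the score `t = X w`, the loading `p = X't / t't`,
#' and `X` and `y` are deflated by the rank-one fits before the next round.
#' Regression coefficients are assembled as `B = W (P'W)^{-1} q` on centered
#' data, so predictions are affine in the input spectrum.  Successive score
#' vectors are mutually orthogonal.
#'
#' @param x a preprocessed [Ramanome-class] or numeric matrix (cells in
#'   rows)
#' @param response numeric response, one value per cell
#' @param nComponents number of latent components
#' @param train logical or integer index of the calibration cells (default
#'   all); the remainder is the validation split.  The conventional split is
#'   biological replicates 1-2 for calibration and replicate 3 for
#'   validation.
#' @param fingerprint wavenumber range used for a `Ramanome` input
#' @return a [PLSRModel-class]
#' @export
plsrFit <- function(x, response, nComponents = 5L, train = NULL,
                    fingerprint = c(640, 1800)) {
  wn <- NULL
  if (is(x, "Ramanome")) {
    x <- cropSpectra(x, fingerprint[1], fingerprint[2])
    wn <- wavenumbers(x)
    x <- scrs(x)
  }
  x <- as.matrix(x)
  if (is.null(wn)) wn <- seq_len(ncol(x))
  response <- as.numeric(response)
  if (length(response) != nrow(x)) stop("response length must match the cell count")
  if (stats::sd(response) == 0) stop("constant response")
  if (is.null(train)) train <- rep(TRUE, nrow(x))
  if (!is.logical(train)) train <- seq_len(nrow(x)) %in% train
  Xtr <- x[train, , drop = FALSE]
  ytr <- response[train]
  nComponents <- as.integer(nComponents)
  if (nComponents < 1L || nComponents > min(nrow(Xtr) - 1L, ncol(Xtr))) {
    stop("nComponents must be in [1, min(N-1, B)]")
  }
  xm <- colMeans(Xtr)
  ym <- mean(ytr)
  X <- sweep(Xtr, 2L, xm)
  y <- ytr - ym
  B <- ncol(X)
  W <- matrix(0, B, nComponents)
  P <- matrix(0, B, nComponents)
  Tm <- matrix(0, nrow(X), nComponents)
  q <- numeric(nComponents)
  for (a in seq_len(nComponents)) {
    w <- crossprod(X, y)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {
      # response fully deflated: stop early at the achieved rank
      nComponents <- a - 1L
      W <- W[, seq_len(nComponents), drop = FALSE]
      P <- P[, seq_len(nComponents), drop = FALSE]
      Tm <- Tm[, seq_len(nComponents), drop = FALSE]
      q <- q[seq_len(nComponents)]
      break
    }
    w <- w / nw
    tt <- as.numeric(X %*% w)
    t2 <- sum(tt^2)
    p <- as.numeric(crossprod(X, tt)) / t2
    qa <- sum(y * tt) / t2
    X <- X - tcrossprod(tt, p)
    y <- y - qa * tt
    W[, a] <- w
    P[, a] <- p
    Tm[, a] <- tt
    q[a] <- qa
  }
  if (nComponents < 1L) stop("response is orthogonal to the spectra")
  coef <- as.numeric(W %*% solve(crossprod(P, W), q))
  intercept <- ym - sum(xm * coef)
  predAll <- as.numeric(x %*% coef) + intercept
  r2 <- function(obs, fit) 1 - sum((obs - fit)^2) / sum((obs - mean(obs))^2)
  r2cal <- r2(response[train], predAll[train])
  r2val <- if (any(!train)) r2(response[!train], predAll[!train]) else NA_real_
  new("PLSRModel",
    nComponents = nComponents, weights = W, scores = Tm, loadings = P,
    coefficients = coef, intercept = intercept, xMean = xm, yMean = ym,
    wavenumbers = as.numeric(wn), r2Calibration = r2cal, r2Validation = r2val
  )
}

#' Predict per-cell response from spectra with a fitted PLSR model
#'
#' @param model a [PLSRModel-class]
#' @param x a [Ramanome-class] on the model's grid, or a numeric matrix
#'   with cells in rows
#' @param fingerprint wavenumber range used for a `Ramanome` input
#' @return numeric predictions, one per cell
#' @export
plsrPredict <- function(model, x, fingerprint = c(640, 1800)) {
  stopifnot(is(model, "PLSRModel"))
  if (is(x, "Ramanome")) {
    x <- cropSpectra(x, fingerprint[1], fingerprint[2])
    if (!isTRUE(all.equal(wavenumbers(x), model@wavenumbers))) {
      stop("grid mismatch between model and spectra")
    }
    x <- scrs(x)
  }
  x <- as.matrix(x)
  if (ncol(x) != length(model@coefficients)) stop("grid mismatch")
  as.numeric(x %*% model@coefficients) + model@intercept
}

#' Choose the PLSR component count by cross-validation on the calibration set
#'
#' Applies the one-standard-error rule: the smallest component count whose
#' cross-validated prediction error is within one standard error of the
#' minimum, which guards against overfitting on small calibration sets.
#'
#' @param x,response,train,fingerprint as in [plsrFit()]
#' @param maxComponents largest component count tried
#' @param folds CV folds (default 5)
#' @param seed RNG seed for the fold assignment
#' @return the selected component count
#' @export
plsrSelectComponents <- function(x, response, maxComponents = 10L, train = NULL,
                                 folds = 5L, seed = 1L, fingerprint = c(640, 1800)) {
  if (is(x, "Ramanome")) x <- scrs(cropSpectra(x, fingerprint[1], fingerprint[2]))
  x <- as.matrix(x)
  if (is.null(train)) train <- rep(TRUE, nrow(x))
  if (!is.logical(train)) train <- seq_len(nrow(x)) %in% train
  X <- x[train, , drop = FALSE]
  y <- response[train]
  maxComponents <- min(maxComponents, nrow(X) - ceiling(nrow(X) / folds) - 1L, ncol(X))
  set.seed(seed)
  fold <- sample(rep_len(seq_len(folds), nrow(X)))
  sqerr <- matrix(NA_real_, nrow(X), maxComponents)
  for (f in seq_len(folds)) {
    te <- fold == f
    for (a in seq_len(maxComponents)) {
      m <- plsrFit(X[!te, , drop = FALSE], y[!te], nComponents = a)
      sqerr[te, a] <- (y[te] - plsrPredict(m, X[te, , drop = FALSE]))^2
    }
  }
  press <- colMeans(sqerr)
  se <- apply(sqerr, 2L, stats::sd) / sqrt(nrow(X))
  best <- which.min(press)
  which(press <= press[best] + se[best])[1L]
}
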