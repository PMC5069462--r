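#' Principal-component linear discriminant analysis (PC-LDA)
#'
#' PCA on the fingerprint bands retaining the smallest number of components
#' whose cumulative variance reaches `varianceRetained` (capped at N - 1 and
#' at N - #classes to keep the LDA well-posed), followed by Fisher LDA on
#' the scores.  `factor1` is the first discriminant axis; per-band
#' contributions are the PC loadings back-projected through the LDA weights.
#'
#' @param x a preprocessed [Ramanome-class] or a numeric matrix
#'   (observations in rows)
#' @param labels class label per observation (>= 2 classes of >= 2)
#' @param varianceRetained cumulative variance fraction (default 0.95)
#' @param fingerprint wavenumber range used for a `Ramanome` input
#' @return list of class `"PcLdaResult"`: `factor1` (scores), `scores` (all
#'   discriminants), `bandContributions`, `nPCs`, `varianceRetained`, `lda`
#' @export
pcLda <- function(x, labels, varianceRetained = 0.95, fingerprint = c(640, 1800)) {
  if (is(x, "Ramanome")) x <- scrs(cropSpectra(x, fingerprint[1], fingerprint[2]))
  labels <- as.factor(labels)
  tab <- table(labels)
  if (length(tab) < 2L || any(tab < 2L)) stop("need >= 2 classes with >= 2 members")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  cumv <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  k <- which(cumv >= varianceRetained)[1L]
  if (is.na(k)) k <- length(cumv)
  kmax <- min(nrow(x) - length(tab), nrow(x) - 1L, ncol(pc$x))
  if (k > kmax) {
    message("capping retained PCs at ", kmax)
    k <- kmax
  }
  sc <- pc$x[, seq_len(k), drop = FALSE]
  ld <- MASS::lda(sc, grouping = labels)
  disc <- sc %*% ld$scaling
  contrib <- pc$rotation[, seq_len(k), drop = FALSE] %*% ld$scaling
  structure(
    list(
      factor1 = disc[, 1L], scores = disc,
      bandContributions = contrib[, 1L], nPCs = k,
      varianceRetained = cumv[k], lda = ld
    ),
    class = "PcLdaResult"
  )
}

#' @export
print.PcLdaResult <- function(x, ...) {
  cat(sprintf(
    "PC-LDA: %d PCs (%.1f%% variance), %d discriminant axes\n",
    x$nPCs, 100 * x$varianceRetained, ncol(x$scores)
  ))
  invisible(x)
}

.stratifiedFolds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in levels(labels)) {
    i <- which(labels == cl)
    fold[i] <- sample(rep_len(seq_len(k), length(i)))
  }
  fold
}

#' Cross-validated Random-Forest classification of SCRS
#'
#' Classifies cells from their band intensities with a Random Forest under
#' stratified k-fold (default) or leave-one-out cross-validation, and
#' reports the pooled confusion matrix, overall accuracy, per-class
#' sensitivity and specificity, and band importances (mean impurity
#' decrease from a forest grown on all cells, ties in the ranking broken
#' toward the lower wavenumber).  Forests are grown with the `ranger`
#' Random-Forest implementation, single-threaded for reproducibility.
#'
#' @param x a preprocessed [Ramanome-class] or numeric matrix
#'   (observations in rows)
#' @param labels class label per observation
#' @param scheme `"kfold"` or `"loo"`
#' @param k folds for `"kfold"` (default 5); every class must have >= k
#'   members
#' @param nTrees trees per forest (default 500)
#' @param seed RNG seed; results are deterministic given the seed
#' @param fingerprint wavenumber range used for a `Ramanome` input
#' @return list of class `"ClassificationReport"`: `confusion`, `accuracy`
#'   (%), `perClass` (`data.frame` with sensitivity/specificity in %),
#'   `importance` (`data.frame` band, importance, rank), `scheme`
#' @export
classifySpectra <- function(x, labels, scheme = c("kfold", "loo"), k = 5L,
                            nTrees = 500L, seed = 1L, fingerprint = c(640, 1800)) {
  scheme <- match.arg(scheme)
  wn <- NULL
  if (is(x, "Ramanome")) {
    x <- cropSpectra(x, fingerprint[1], fingerprint[2])
    wn <- wavenumbers(x)
    x <- scrs(x)
  }
  x <- as.matrix(x)
  labels <- droplevels(as.factor(labels))
  tab <- table(labels)
  if (length(tab) < 2L) stop("need >= 2 classes")
  set.seed(seed)
  if (scheme == "kfold") {
    if (any(tab < k)) stop("every class needs >= k members for k-fold CV")
    fold <- .stratifiedFolds(labels, k)
  } else {
    fold <- seq_along(labels)
    k <- length(labels)
  }
  colnames(x) <- paste0("b", seq_len(ncol(x)))
  pred <- factor(rep(NA_character_, length(labels)), levels = levels(labels))
  for (f in seq_len(k)) {
    te <- fold == f
    fit <- ranger::ranger(
      x = x[!te, , drop = FALSE], y = labels[!te],
      num.trees = nTrees, seed = seed + f, num.threads = 1L
    )
    pred[te] <- stats::predict(fit, x[te, , drop = FALSE], num.threads = 1L)$predictions
  }
  confusion <- table(truth = labels, predicted = pred)
  acc <- 100 * sum(diag(confusion)) / sum(confusion)
  perClass <- do.call(rbind, lapply(levels(labels), function(cl) {
    tp <- confusion[cl, cl]
    fn <- sum(confusion[cl, ]) - tp
    fp <- sum(confusion[, cl]) - tp
    tn <- sum(confusion) - tp - fn - fp
    data.frame(
      class = cl, n = sum(confusion[cl, ]),
      sensitivity = 100 * tp / (tp + fn),
      specificity = 100 * tn / (tn + fp)
    )
  }))
  full <- ranger::ranger(
    x = x, y = labels, num.trees = nTrees, seed = seed,
    num.threads = 1L, importance = "impurity"
  )
  imp <- as.numeric(full$variable.importance)
  band <- if (is.null(wn)) seq_along(imp) else wn
  ord <- order(-imp, band)
  importance <- data.frame(band = band, importance = imp)[ord, ]
  importance$rank <- seq_len(nrow(importance))
  structure(
    list(
      confusion = confusion, accuracy = acc, perClass = perClass,
      importance = importance, scheme = if (scheme == "kfold") paste0(k, "-fold") else "loo"
    ),
    class = "ClassificationReport"
  )
}

#' @export
print.ClassificationReport <- function(x, ...) {
  cat(sprintf(
    "Random-Forest classification (%s CV): accuracy %.1f%%\n",
    x$scheme, x$accuracy
  ))
  print(x$confusion)
  print(x$perClass, row.names = FALSE)
  invisible(x)
}
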