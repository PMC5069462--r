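#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

#' Ramanome: a collection of single-cell Raman spectra
#'
#' A `Ramanome` holds the single-cell Raman spectra (SCRS) of N cells sampled
#' from an isogenic population, measured on a shared wavenumber grid of B
#' bands, together with per-cell condition metadata.  It extends
#' [SummarizedExperiment::SummarizedExperiment] with bands as rows (the
#' wavenumber grid lives in `rowData()$wavenumber`) and cells as columns.
#'
#' The per-cell metadata (`colData`) carries at least `cell_id`, `stressor`,
#' `dose`, `dose_unit`, `time_min`, `replicate` and `strain`.  A `Ramanome`
#' is either `"raw"` (as loaded or simulated) or `"preprocessed"`, in which
#' case every spectrum is baseline-corrected, non-negative and has unit
#' Euclidean norm.
#'
#' @slot processingState `"raw"` or `"preprocessed"`.
#' @seealso [Ramanome()], [readRamanome()], [preprocessRamanome()]
#' @export
setClass("Ramanome",
  contains = "SummarizedExperiment",
  slots = c(processingState = "character"),
  prototype = prototype(processingState = "raw")
)

.validRamanome <- function(object) {
  msg <- character()
  w <- rowData(object)$wavenumber
  if (is.null(w)) {
    return("rowData must contain a 'wavenumber' column")
  }
  if (length(w) < 2L) msg <- c(msg, "wavenumber grid needs >= 2 bands")
  if (any(!is.finite(w)) || any(w <= 0)) {
    msg <- c(msg, "wavenumbers must be finite and positive")
  }
  if (any(diff(w) <= 0)) msg <- c(msg, "wavenumbers must be strictly increasing")
  x <- assay(object)
  if (ncol(x) < 1L) msg <- c(msg, "a Ramanome needs at least one cell")
  if (anyNA(x)) msg <- c(msg, "intensities must not contain NA (a SCRS is a complete scan)")
  cd <- colData(object)
  need <- c("cell_id", "stressor", "dose", "time_min", "replicate")
  miss <- setdiff(need, colnames(cd))
  if (length(miss)) {
    msg <- c(msg, paste0("missing cell metadata column(s): ", paste(miss, collapse = ", ")))
  } else {
    if (anyDuplicated(cd$cell_id)) msg <- c(msg, "duplicate cell ids")
    if (any(cd$time_min < 0)) msg <- c(msg, "time_min must be >= 0")
    bad <- cd$stressor == "none" & cd$dose != 0
    if (any(bad)) msg <- c(msg, "stressor 'none' implies dose 0")
  }
  st <- object@processingState
  if (!length(st) == 1L || !st %in% c("raw", "preprocessed")) {
    msg <- c(msg, "processingState must be 'raw' or 'preprocessed'")
  } else if (st == "preprocessed" && ncol(x) > 0L) {
    nrm <- sqrt(colSums(x^2))
    if (any(abs(nrm - 1) > 1e-6) && any(abs(colSums(x) - 1) > 1e-6)) {
      msg <- c(msg, "preprocessed spectra must have unit L2 norm or unit area")
    }
    if (min(x) < -1e-9) {
      msg <- c(msg, "preprocessed spectra must be non-negative (baseline-residual tolerance 1e-9)")
    }
  }
  if (length(msg)) msg else TRUE
}
setValidity("Ramanome", .validRamanome)

#' Construct a Ramanome from a spectra matrix and cell metadata
#'
#' @param spectra numeric matrix of intensities with cells in rows and
#'   wavenumbers in columns (the usual instrument wide-table orientation).
#' @param wavenumbers numeric vector of wavenumbers (cm^-1), one per column
#'   of `spectra`.  May be supplied in descending order; columns are reordered
#'   so the grid is stored ascending.
#' @param cells `data.frame` of per-cell metadata with columns `cell_id`,
#'   `stressor`, `dose`, `dose_unit`, `time_min`, `replicate` and optionally
#'   `strain` (default `"WT"`).
#' @param processingState `"raw"` (default) or `"preprocessed"`.
#' @return a [Ramanome-class] object.
#' @examples
#' m <- matrix(runif(2 * 5) + 1, nrow = 2)
#' cells <- data.frame(cell_id = c("a", "b"), stressor = "none", dose = 0,
#'                     dose_unit = "", time_min = 0, replicate = 1)
#' Ramanome(m, seq(600, 1800, length.out = 5), cells)
#' @export
Ramanome <- function(spectra, wavenumbers, cells, processingState = "raw") {
  spectra <- as.matrix(spectra)
  wavenumbers <- as.numeric(wavenumbers)
  if (ncol(spectra) != length(wavenumbers)) {
    stop("ncol(spectra) must equal length(wavenumbers)")
  }
  if (is.unsorted(wavenumbers, strictly = TRUE)) {
    # instruments export either grid order; store ascending
    if (is.unsorted(rev(wavenumbers), strictly = TRUE)) {
      stop("wavenumber grid is not monotone")
    }
    ord <- rev(seq_along(wavenumbers))
    wavenumbers <- wavenumbers[ord]
    spectra <- spectra[, ord, drop = FALSE]
  }
  cells <- as.data.frame(cells)
  if (is.null(cells$strain)) cells$strain <- "WT"
  if (is.null(cells$dose_unit)) cells$dose_unit <- ""
  cells$cell_id <- as.character(cells$cell_id)
  x <- t(spectra)
  dimnames(x) <- list(NULL, cells$cell_id)
  se <- SummarizedExperiment(
    assays = SimpleList(intensities = x),
    rowData = DataFrame(wavenumber = wavenumbers),
    colData = DataFrame(cells, row.names = cells$cell_id)
  )
  new("Ramanome", se, processingState = processingState)
}

#' @describeIn Ramanome the wavenumber grid (ascending, cm^-1)
#' @param object,x a `Ramanome`
#' @export
setGeneric("wavenumbers", function(x) standardGeneric("wavenumbers"))

#' @rdname Ramanome
#' @export
setMethod("wavenumbers", "Ramanome", function(x) rowData(x)$wavenumber)

#' @describeIn Ramanome the N x B spectra matrix (cells in rows)
#' @export
setGeneric("scrs", function(x) standardGeneric("scrs"))

#' @rdname Ramanome
#' @export
setMethod("scrs", "Ramanome", function(x) t(assay(x, "intensities")))

#' @describeIn Ramanome per-cell metadata as a plain `data.frame`
#' @export
setGeneric("cellData", function(x) standardGeneric("cellData"))

#' @rdname Ramanome
#' @export
setMethod("cellData", "Ramanome", function(x) as.data.frame(colData(x)))

#' @describeIn Ramanome processing state, `"raw"` or `"preprocessed"`
#' @export
setGeneric("processingState", function(x) standardGeneric("processingState"))

#' @rdname Ramanome
#' @export
setMethod("processingState", "Ramanome", function(x) x@processingState)

setMethod("show", "Ramanome", function(object) {
  w <- wavenumbers(object)
  cat(sprintf(
    "Ramanome: %d cells x %d bands (%.1f-%.1f cm-1), %s\n",
    ncol(object), nrow(object), min(w), max(w), object@processingState
  ))
  cd <- colData(object)
  cat("  stressors:", paste(unique(cd$stressor), collapse = ", "), "\n")
  cat("  time points (min):", paste(sort(unique(cd$time_min)), collapse = ", "), "\n")
})

#' Band annotation table
#'
#' Maps Raman wavenumbers to chemical categories (`nucleic_acid`, `protein`,
#' `lipid`, `carbohydrate`, `other`).  Lookups match the nearest annotated
#' band within `tolerance` cm^-1; ties break toward the lower wavenumber.
#'
#' @slot table `data.frame` with columns `wavenumber`, `category`,
#'   `description`.
#' @slot tolerance matching tolerance in cm^-1.
#' @seealso [annotateBand()], [defaultBandAnnotation()]
#' @export
setClass("BandAnnotation",
  slots = c(table = "data.frame", tolerance = "numeric")
)

.bandCategories <- c("nucleic_acid", "protein", "lipid", "carbohydrate", "other")

setValidity("BandAnnotation", function(object) {
  msg <- character()
  tb <- object@table
  if (!all(c("wavenumber", "category", "description") %in% colnames(tb))) {
    msg <- c(msg, "table needs columns wavenumber, category, description")
  } else if (!all(tb$category %in% .bandCategories)) {
    msg <- c(msg, paste0("category must be one of: ", paste(.bandCategories, collapse = ", ")))
  }
  if (length(object@tolerance) != 1L || object@tolerance <= 0) {
    msg <- c(msg, "tolerance must be a single positive number")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "BandAnnotation", function(object) {
  cat(sprintf(
    "BandAnnotation: %d bands, tolerance %.1f cm-1\n",
    nrow(object@table), object@tolerance
  ))
  print(table(object@table$category))
})

#' Partial-least-squares calibration model (NIPALS PLS1)
#'
#' Latent-variable calibration mapping preprocessed spectra to a per-cell
#' scalar response (e.g. lipid or DNA density).  Fitted by [plsrFit()];
#' predictions via [plsrPredict()] are affine in the input spectrum.
#'
#' @slot nComponents number of latent components.
#' @slot weights,scores,loadings NIPALS weight/score/loading matrices.
#' @slot coefficients regression coefficient per band.
#' @slot intercept scalar intercept.
#' @slot xMean,yMean centering constants.
#' @slot wavenumbers the grid the model was trained on.
#' @slot r2Calibration,r2Validation coefficient of determination on the
#'   calibration split and the held-out split (NA if no hold-out).
#' @export
setClass("PLSRModel", slots = c(
  nComponents = "integer",
  weights = "matrix", scores = "matrix", loadings = "matrix",
  coefficients = "numeric", intercept = "numeric",
  xMean = "numeric", yMean = "numeric",
  wavenumbers = "numeric",
  r2Calibration = "numeric", r2Validation = "numeric"
))

setMethod("show", "PLSRModel", function(object) {
  cat(sprintf(
    "PLSRModel: %d components over %d bands\n  R2 calibration = %.3f, R2 validation = %s\n",
    object@nComponents, length(object@coefficients), object@r2Calibration,
    ifelse(is.na(object@r2Validation), "NA", sprintf("%.3f", object@r2Validation))
  ))
})

#' Raman barcode of cellular response to stressors (RBCS)
#'
#' A signed barcode over a pooled set of marker bands: for each stressor,
#' band and time point the entry is +1 (significantly increased intensity
#' versus the matched control), -1 (significantly decreased) or 0.
#'
#' @slot bands marker wavenumbers, ascending.
#' @slot signs list (one matrix per stressor) of band x time sign matrices.
#' @slot times time axis in minutes.
#' @slot categories chemical category per band.
#' @slot sharing per-band sharing table (which stressors include the band,
#'   and its sharing class: `all_shared`, `shared`, or `specific`).
#' @seealso [buildRBCS()], [clusterRBCS()], [sharingAnalysis()]
#' @export
setClass("RBCS", slots = c(
  bands = "numeric", signs = "list", times = "numeric",
  categories = "character", sharing = "data.frame"
))

setValidity("RBCS", function(object) {
  msg <- character()
  if (is.unsorted(object@bands, strictly = TRUE)) {
    msg <- c(msg, "bands must be ascending and unique")
  }
  ok <- vapply(object@signs, function(m) {
    all(dim(m) == c(length(object@bands), length(object@times))) &&
      all(m %in% c(-1, 0, 1))
  }, logical(1))
  if (!all(ok)) msg <- c(msg, "each sign matrix must be bands x times with entries in {-1,0,+1}")
  if (length(msg)) msg else TRUE
})

setMethod("show", "RBCS", function(object) {
  cat(sprintf(
    "RBCS: %d stressors x %d marker bands x %d time points\n",
    length(object@signs), length(object@bands), length(object@times)
  ))
  cat("  stressors:", paste(names(object@signs), collapse = ", "), "\n")
  cat("  sharing:", paste(names(table(object@sharing$class)),
    table(object@sharing$class),
    sep = "=", collapse = ", "
  ), "\n")
})
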