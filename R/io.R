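.detectDelim <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (lengths(regmatches(hdr, gregexpr("\t", hdr))) >=
    lengths(regmatches(hdr, gregexpr(",", hdr)))) "\t" else ","
}

#' Read a ramanome from a wide spectra table plus a cell-metadata table
#'
#' The spectra table is delimiter-separated (comma or tab, auto-detected):
#' first row holds the wavenumbers (ascending or descending), first column
#' the cell ids, remaining values the intensities in arbitrary units.  The
#' metadata table is keyed by `cell_id` and must carry `stressor`, `dose`,
#' `dose_unit`, `time_min`, `replicate` and optionally `strain` and
#' `processing_state`.
#'
#' @param spectraPath,metadataPath paths to the two tables.
#' @return a raw-state [Ramanome-class] (or preprocessed, if the metadata
#'   records a uniform `processing_state` of `"preprocessed"`).
#' @export
readRamanome <- function(spectraPath, metadataPath) {
  sdl <- .detectDelim(spectraPath)
  sp <- utils::read.table(spectraPath,
    sep = sdl, header = TRUE, check.names = FALSE,
    row.names = NULL, stringsAsFactors = FALSE
  )
  ids <- as.character(sp[[1L]])
  if (anyDuplicated(ids)) stop("duplicate cell ids in spectra table")
  w <- suppressWarnings(as.numeric(colnames(sp)[-1L]))
  if (anyNA(w)) stop("non-numeric wavenumber column headers in spectra table")
  m <- as.matrix(sp[, -1L, drop = FALSE])
  if (!is.numeric(m) || anyNA(m)) stop("non-numeric or missing intensity values")
  mdl <- .detectDelim(metadataPath)
  md <- utils::read.table(metadataPath,
    sep = mdl, header = TRUE, check.names = FALSE, stringsAsFactors = FALSE
  )
  if (!"cell_id" %in% colnames(md)) stop("metadata table must contain cell_id")
  md$cell_id <- as.character(md$cell_id)
  miss <- setdiff(ids, md$cell_id)
  if (length(miss)) {
    stop("no metadata for cell id(s): ", paste(utils::head(miss, 5L), collapse = ", "))
  }
  md <- md[match(ids, md$cell_id), , drop = FALSE]
  state <- "raw"
  if (!is.null(md$processing_state)) {
    st <- unique(md$processing_state)
    if (length(st) == 1L && st %in% c("raw", "preprocessed")) state <- st
    md$processing_state <- NULL
  }
  dimnames(m) <- NULL
  Ramanome(m, w, md, processingState = state)
}

#' Write a ramanome as spectra and metadata CSV tables
#'
#' Emits `spectra.csv` (cells x wavenumbers, full double precision) and
#' `metadata.csv` into `outDir`; [readRamanome()] on the two files
#' reproduces the object.
#'
#' @param r a [Ramanome-class]
#' @param outDir output directory (created if absent)
#' @return invisibly, the two file paths.
#' @export
writeRamanome <- function(r, outDir) {
  stopifnot(is(r, "Ramanome"))
  if (ncol(r) < 1L) stop("empty cell list")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  spPath <- file.path(outDir, "spectra.csv")
  mdPath <- file.path(outDir, "metadata.csv")
  m <- scrs(r)
  out <- cbind(
    cell_id = cellData(r)$cell_id,
    as.data.frame(format(m, digits = 17L, trim = TRUE, scientific = TRUE))
  )
  colnames(out) <- c("cell_id", format(wavenumbers(r), digits = 17L, trim = TRUE))
  utils::write.table(out, spPath, sep = ",", row.names = FALSE, quote = FALSE)
  md <- cellData(r)
  md$processing_state <- processingState(r)
  utils::write.table(md, mdPath, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(c(spectra = spPath, metadata = mdPath))
}

#' Read a band-annotation table
#'
#' @param path CSV with columns `wavenumber`, `category`, `description`.
#' @param tolerance matching tolerance in cm^-1 (default 4; nearby synonyms
#'   such as 1445/1448 cm^-1 name the same lipid band).
#' @return a [BandAnnotation-class]
#' @export
readBandAnnotation <- function(path, tolerance = 4) {
  tb <- utils::read.csv(path, stringsAsFactors = FALSE)
  tb <- tb[order(tb$wavenumber), , drop = FALSE]
  new("BandAnnotation", table = tb, tolerance = tolerance)
}

#' The packaged band-annotation table
#'
#' Standard assignments of fingerprint-region Raman bands of bacterial cells
#' to nucleic-acid, protein, lipid and carbohydrate categories (e.g.
#' 782 cm^-1 cytosine/uracil ring stretching, 1002 cm^-1 phenylalanine ring
#' breathing, 1445 cm^-1 lipid CH2 bending).
#'
#' @param tolerance matching tolerance in cm^-1.
#' @return a [BandAnnotation-class]
#' @export
defaultBandAnnotation <- function(tolerance = 4) {
  readBandAnnotation(
    system.file("extdata", "band_annotations.csv", package = "ramanome", mustWork = TRUE),
    tolerance = tolerance
  )
}

#' Annotate a wavenumber with its chemical category
#'
#' Returns the category and description of the nearest annotated band within
#' the annotation's tolerance; ties break toward the lower wavenumber.  A
#' wavenumber with no entry in range yields category `"unannotated"` rather
#' than an error.
#'
#' @param ann a [BandAnnotation-class]
#' @param wavenumber numeric vector of query wavenumbers (cm^-1)
#' @return `data.frame` with columns `query`, `matched` (NA if none),
#'   `category`, `description`.
#' @examples
#' annotateBand(defaultBandAnnotation(), c(1002, 782, 1700))
#' @export
annotateBand <- function(ann, wavenumber) {
  stopifnot(is(ann, "BandAnnotation"))
  tb <- ann@table
  res <- lapply(wavenumber, function(w) {
    d <- abs(tb$wavenumber - w)
    ok <- which(d <= ann@tolerance)
    if (!length(ok)) {
      return(data.frame(
        query = w, matched = NA_real_,
        category = "unannotated", description = NA_character_
      ))
    }
    # nearest entry wins; ties toward the lower wavenumber
    i <- ok[order(d[ok], tb$wavenumber[ok])][1L]
    data.frame(
      query = w, matched = tb$wavenumber[i],
      category = tb$category[i], description = tb$description[i]
    )
  })
  do.call(rbind, res)
}

#' Locate grid indices nearest to nominal band positions
#'
#' @param grid ascending wavenumber grid
#' @param bands nominal band positions (cm^-1)
#' @param tolerance maximal allowed distance; an out-of-tolerance band errors.
#' @return integer indices into `grid`
#' @export
matchBands <- function(grid, bands, tolerance = 4) {
  idx <- vapply(bands, function(b) which.min(abs(grid - b)), integer(1))
  off <- abs(grid[idx] - bands)
  if (any(off > tolerance)) {
    stop(
      "band(s) not on grid within tolerance: ",
      paste(bands[off > tolerance], collapse = ", ")
    )
  }
  idx
}
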