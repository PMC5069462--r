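#' Build a Raman barcode of cellular response to stressors (RBCS)
#'
#' Pools the per-stressor marker bands; if the pooled set exceeds
#' `targetSize`, the bands with the largest summed importance across
#' stressors are kept (ties toward the lower wavenumber).  For each
#' stressor, band and time point the barcode entry is the significance sign
#' call (+1 increased, -1 decreased, 0 not significant) from the supplied
#' [bandTests()] results.  The sharing table classes every band as
#' `all_shared` (marker for every stressor), `shared` (>= 2 stressors) or
#' `specific`.
#'
#' @param markerSets named list (one per stressor) of [significantBands()]
#'   results
#' @param signCalls named list (one per stressor) of per-time lists of
#'   [bandTests()] results, aligned with `times`
#' @param times time axis in minutes
#' @param targetSize maximal barcode size (default 31)
#' @param minSeparation minimal spacing between selected bands in cm^-1
#'   (default 8): profiles are measured on a dense grid that oversamples
#'   each physical band, so selection keeps only the strongest grid point
#'   per band region
#' @param annotation optional [BandAnnotation-class] for band categories
#' @return an [RBCS-class]
#' @export
buildRBCS <- function(markerSets, signCalls, times, targetSize = 31L,
                      minSeparation = 8, annotation = NULL) {
  if (length(markerSets) < 2L) stop("need markers for >= 2 stressors")
  stressors <- names(markerSets)
  pool <- sort(unique(unlist(lapply(markerSets, function(m) m$wavenumber))))
  if (!length(pool)) stop("empty marker pool")
  imp <- vapply(pool, function(w) {
    sum(vapply(markerSets, function(m) {
      i <- match(w, m$wavenumber)
      if (is.na(i)) 0 else m$importance[i]
    }, numeric(1)))
  }, numeric(1))
  # greedy: strongest summed importance first (ties toward the lower
  # wavenumber), skipping anything within minSeparation of a kept band
  kept <- numeric(0)
  for (i in order(-imp, pool)) {
    if (length(kept) >= targetSize) break
    if (!length(kept) || all(abs(kept - pool[i]) >= minSeparation)) {
      kept <- c(kept, pool[i])
    }
  }
  pool <- sort(kept)
  signs <- lapply(stressors, function(s) {
    m <- matrix(0, length(pool), length(times),
      dimnames = list(pool, paste0("t", times))
    )
    for (j in seq_along(times)) {
      if (times[j] == 0) next
      bt <- signCalls[[s]][[j]]
      i <- matchBands(bt$wavenumber, pool)
      m[, j] <- bt$sign[i]
    }
    # barcode entries are nonzero only for this stressor's own markers
    m[!pool %in% markerSets[[s]]$wavenumber, ] <- 0
    m
  })
  names(signs) <- stressors
  membership <- vapply(
    markerSets, function(m) pool %in% m$wavenumber,
    logical(length(pool))
  )
  nShared <- rowSums(membership)
  sharing <- data.frame(
    wavenumber = pool,
    stressors = apply(membership, 1L, function(b) paste(stressors[b], collapse = ",")),
    n_stressors = nShared,
    class = ifelse(nShared == length(stressors), "all_shared",
      ifelse(nShared >= 2, "shared", "specific")
    )
  )
  cats <- if (is.null(annotation)) {
    rep(NA_character_, length(pool))
  } else {
    annotateBand(annotation, pool)$category
  }
  new("RBCS",
    bands = pool, signs = signs, times = as.numeric(times),
    categories = cats, sharing = sharing
  )
}

#' Mechanism-based clustering of stressors from their barcodes
#'
#' Each stressor's signed barcode is flattened to a vector (by default the
#' time-collapsed majority sign per band) and stressors are clustered by
#' average-linkage agglomeration on Hamming (default, proportion of
#' differing entries) or Euclidean distances.
#'
#' @param rbcs an [RBCS-class] with >= 3 stressors
#' @param metric `"hamming"` or `"euclidean"`
#' @param collapse collapse the time axis to a majority sign per band
#'   (default `TRUE`); otherwise the full band x time matrix is used
#' @return list of class `"StressorDendrogram"`: `hclust`, `dist`,
#'   `newick` (Newick string via [ape::write.tree()]), `metric`
#' @export
clusterRBCS <- function(rbcs, metric = c("hamming", "euclidean"), collapse = TRUE) {
  stopifnot(is(rbcs, "RBCS"))
  metric <- match.arg(metric)
  if (length(rbcs@signs) < 3L) stop("need >= 3 stressors for a nontrivial tree")
  vecs <- t(vapply(rbcs@signs, function(m) {
    if (collapse) {
      apply(m, 1L, function(s) {
        s <- s[s != 0]
        if (!length(s)) 0 else if (sum(s > 0) >= sum(s < 0)) 1 else -1
      })
    } else {
      as.numeric(m)
    }
  }, numeric(if (collapse) length(rbcs@bands) else length(rbcs@bands) * length(rbcs@times))))
  d <- if (metric == "hamming") {
    n <- nrow(vecs)
    dm <- matrix(0, n, n, dimnames = list(rownames(vecs), rownames(vecs)))
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        dm[i, j] <- dm[j, i] <- mean(vecs[i, ] != vecs[j, ])
      }
    }
    stats::as.dist(dm)
  } else {
    stats::dist(vecs)
  }
  if (all(d == 0)) warning("all stressor barcodes are identical; degenerate tree")
  hc <- stats::hclust(d, method = "average")
  structure(
    list(
      hclust = hc, dist = d,
      newick = ape::write.tree(ape::as.phylo(hc)), metric = metric
    ),
    class = "StressorDendrogram"
  )
}

#' @export
print.StressorDendrogram <- function(x, ...) {
  cat("Stressor dendrogram (average linkage,", x$metric, "distance):\n ", x$newick, "\n")
  invisible(x)
}

#' Shared and specific marker bands between stressors and categories
#'
#' Pairwise overlap counts (and identities) of marker-band sets, per
#' stressor pair and per stressor-category pair, plus the all-shared set.
#' Accepts either an [RBCS-class] or a plain named list of band vectors.
#'
#' @param x an `RBCS` or a named list of numeric band vectors
#' @param groups named character: stressor -> category (e.g.
#'   `c(Eth = "alcohol", Cu = "metal")`); optional
#' @return list of class `"SharingAnalysis"`: `pairwise` (`data.frame` of
#'   stressor pairs with `shared` counts and band identities), `allShared`,
#'   `groupPairwise` (category-pair overlap, if `groups` given)
#' @export
sharingAnalysis <- function(x, groups = NULL) {
  sets <- if (is(x, "RBCS")) {
    lapply(stats::setNames(names(x@signs), names(x@signs)), function(s) {
      x@sharing$wavenumber[grepl(paste0("(^|,)", s, "(,|$)"), x@sharing$stressors)]
    })
  } else {
    x
  }
  if (is.null(names(sets))) stop("band sets must be named by stressor")
  stressors <- names(sets)
  prs <- utils::combn(stressors, 2L, simplify = FALSE)
  pairwise <- do.call(rbind, lapply(prs, function(p) {
    ov <- intersect(sets[[p[1]]], sets[[p[2]]])
    data.frame(
      a = p[1], b = p[2], shared = length(ov),
      bands = paste(sort(ov), collapse = ",")
    )
  }))
  allShared <- Reduce(intersect, sets)
  groupPairwise <- NULL
  if (!is.null(groups)) {
    if (!all(stressors %in% names(groups))) stop("groups must cover all stressors")
    gsets <- lapply(split(stressors, groups[stressors]), function(ss) {
      sort(unique(unlist(sets[ss])))
    })
    gp <- utils::combn(names(gsets), 2L, simplify = FALSE)
    groupPairwise <- do.call(rbind, lapply(gp, function(p) {
      ov <- intersect(gsets[[p[1]]], gsets[[p[2]]])
      data.frame(
        a = p[1], b = p[2], shared = length(ov),
        bands = paste(sort(ov), collapse = ",")
      )
    }))
  }
  structure(
    list(pairwise = pairwise, allShared = sort(allShared), groupPairwise = groupPairwise),
    class = "SharingAnalysis"
  )
}

#' @export
print.SharingAnalysis <- function(x, ...) {
  cat(
    "All-shared bands (", length(x$allShared), "):",
    paste(x$allShared, collapse = ", "), "\n"
  )
  print(x$pairwise[, c("a", "b", "shared")], row.names = FALSE)
  invisible(x)
}
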