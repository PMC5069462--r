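.writeTsv <- function(x, dir, name) {
  utils::write.table(x, file.path(dir, name),
    sep = "\t", row.names = FALSE,
    quote = FALSE
  )
}

# ANOSIM of each nonzero level of `by` against the matched control cells
.anosimLadder <- function(r, by, nPerm = 999L, seed = 1L) {
  cd <- cellData(r)
  ctrl <- cd$stressor == "none"
  lv <- sort(unique(cd[[by]][!ctrl]))
  do.call(rbind, lapply(lv, function(v) {
    sel <- (!ctrl & cd[[by]] == v) |
      (ctrl & (by != "time_min" | cd$time_min == v))
    sub <- r[, sel]
    lab <- cellData(sub)$stressor != "none"
    a <- anosimTest(sub, lab, nPerm = nPerm, seed = seed)
    data.frame(level = v, R = a$R, p = a$p)
  }))
}

#' Run a named end-to-end analysis workflow
#'
#' Simulates the named scenario, preprocesses it, runs the matching
#' analysis chain and writes TSV tables plus a machine-readable
#' `summary.json` into `outDir`.
#'
#' * `dose_response` — ANOSIM R and p per ethanol dose versus control, the
#'   Pearson R^2 of R against dose, SDM reproducibility and the
#'   cross-validated dose-classification accuracy.
#' * `duration_response` — ANOSIM R per exposure time, R^2 of R against
#'   time within the first hour, and time-point classification accuracy
#'   with per-class sensitivity/specificity.
#' * `six_stressors` — six-stressor classification, per-stressor marker
#'   bands with temporal K-means clusters, the pooled RBCS with its
#'   stressor dendrogram and sharing table, and heterogeneity (RSD) at the
#'   782 cm^-1 nucleic-acid band.
#' * `resistance_specificity` — stressed-versus-control ANOSIM for
#'   sensitive and resistant strains under kanamycin, strain-level
#'   classification, and the 782 cm^-1 heterogeneity contrast.
#'
#' @param name workflow name
#' @param seed seed for simulation, permutation and cross-validation
#' @param outDir output directory
#' @param cellsPerCondition,replicates scenario sizes (defaults 20 and 3)
#' @param nPerm ANOSIM permutations (default 999)
#' @return invisibly, the summary list (also serialized as JSON)
#' @export
runWorkflow <- function(name = c(
                          "dose_response", "duration_response",
                          "six_stressors", "resistance_specificity"
                        ),
                        seed = 1L, outDir = tempfile("ramanome_run_"),
                        cellsPerCondition = 20L, replicates = 3L, nPerm = 999L) {
  name <- match.arg(name)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  tdir <- file.path(outDir, "tables")
  dir.create(tdir, showWarnings = FALSE)
  ann <- defaultBandAnnotation()
  summary <- list(workflow = name, seed = seed)

  scen <- switch(name,
    dose_response = "eth_dose", duration_response = "eth_time",
    six_stressors = "six_stressors", resistance_specificity = "kan_resistance"
  )
  design <- scenarioLibrary(scen,
    seed = seed,
    cellsPerCondition = cellsPerCondition, replicates = replicates
  )
  sim <- simulateRamanome(design)
  pp <- preprocessRamanome(sim$ramanome)
  cd <- cellData(pp)

  if (name == "dose_response") {
    lad <- .anosimLadder(pp, "dose", nPerm = nPerm, seed = seed)
    .writeTsv(lad, tdir, "anosim_by_dose.tsv")
    fit <- stats::cor(lad$R, lad$level)^2
    sdmv <- sdmReproducibility(pp[, cd$stressor == "none"])
    cls <- classifySpectra(pp, factor(cd$dose), k = 5L, seed = seed)
    summary$anosim_R <- stats::setNames(lad$R, lad$level)
    summary$pearson_r2_R_vs_dose <- fit
    summary$dose_classification_accuracy <- cls$accuracy
    summary$sdm <- c(mean = sdmv$sdmMean, sd = sdmv$sdmSd)
  } else if (name == "duration_response") {
    lad <- .anosimLadder(pp[, cd$time_min > 0], "time_min", nPerm = nPerm, seed = seed)
    .writeTsv(lad, tdir, "anosim_by_time.tsv")
    early <- lad[lad$level <= 60, ]
    summary$anosim_R <- stats::setNames(lad$R, lad$level)
    summary$pearson_r2_R_vs_time_1h <- stats::cor(early$R, early$level)^2
    stressedLate <- cd$stressor != "none" & cd$time_min > 0
    cls <- classifySpectra(
      pp[, stressedLate], factor(cd$time_min[stressedLate]),
      k = 5L, seed = seed
    )
    .writeTsv(cls$perClass, tdir, "timepoint_classification.tsv")
    summary$time_classification_accuracy <- cls$accuracy
    summary$min_sensitivity <- min(cls$perClass$sensitivity)
    summary$min_specificity <- min(cls$perClass$specificity)
  } else if (name == "six_stressors") {
    at30 <- cd$time_min == 30 & cd$stressor != "none"
    cls <- classifySpectra(pp[, at30], factor(cd$stressor[at30]), k = 5L, seed = seed)
    summary$stressor_classification_accuracy <- cls$accuracy
    stressors <- setdiff(unique(cd$stressor), "none")
    times <- sort(unique(cd$time_min))
    markerSets <- list()
    signCalls <- list()
    for (s in stressors) {
      sl <- lapply(times, function(t) pp[, cd$stressor == s & cd$time_min == t])
      clc <- lapply(times, function(t) pp[, cd$stressor == "none" & cd$time_min == t])
      prof <- dValueProfiles(sl, clc, times, stressor = s)
      tests <- lapply(seq_along(times), function(j) bandTests(sl[[j]], clc[[j]]))
      mk <- significantBands(prof, tests, annotation = ann)
      markerSets[[s]] <- mk
      signCalls[[s]] <- tests
      if (nrow(mk) > max(5L, 4L)) {
        tc <- clusterTemporal(prof,
          bands = utils::head(mk$wavenumber, 50L),
          seed = seed, annotation = ann
        )
        .writeTsv(
          data.frame(
            band = tc$bands, cluster = tc$cluster,
            silhouette = tc$silhouette
          ),
          tdir, paste0("clusters_", s, ".tsv")
        )
        summary[[paste0("silhouette_", s)]] <- tc$silhouette
      }
      .writeTsv(mk, tdir, paste0("markers_", s, ".tsv"))
    }
    rb <- buildRBCS(markerSets, signCalls, times, annotation = ann)
    dg <- clusterRBCS(rb)
    sh <- sharingAnalysis(rb, groups = c(
      Eth = "alcohol", nBut = "alcohol",
      Amp = "antibiotic", Kan = "antibiotic", Cu = "metal", Cr = "metal"
    ))
    writeLines(dg$newick, file.path(tdir, "stressor_dendrogram.nwk"))
    .writeTsv(rb@sharing, tdir, "rbcs_sharing.tsv")
    summary$rbcs_n_bands <- length(rb@bands)
    summary$rbcs_all_shared <- sh$allShared
    summary$dendrogram <- dg$newick
    het <- lapply(
      stats::setNames(stressors, stressors),
      function(s) {
        lapply(
          splitRamanome(pp[, cd$stressor == s & cd$time_min == 300], "replicate"),
          rsdProfile
        )
      }
    )
    hc <- heterogeneityCompare(het, 782)
    summary$heterogeneity_782_p <- hc$p
  } else { # resistance_specificity
    grp <- paste(cd$strain, ifelse(cd$stressor == "none", "H2O", cd$stressor), sep = "+")
    at30 <- cd$time_min == 30
    cls <- classifySpectra(pp[, at30], factor(grp[at30]), k = 5L, seed = seed)
    summary$condition_classification_accuracy <- cls$accuracy
    for (st in c("WT", "Kans", "Kanr")) {
      # contrast at 180 min, near the kanamycin response peak
      sel <- cd$time_min == 180 & ((cd$strain == st & cd$stressor == "Kan") |
        (cd$strain == "WT" & cd$stressor == "none"))
      if (sum(cd$strain == st & cd$stressor == "Kan") == 0) next
      a <- anosimTest(
        pp[, sel], cellData(pp[, sel])$stressor != "none",
        nPerm = nPerm, seed = seed
      )
      summary[[paste0("anosim_R_", st, "_Kan_vs_control")]] <- a$R
      summary[[paste0("anosim_p_", st, "_Kan_vs_control")]] <- a$p
    }
    het <- lapply(
      split(seq_len(ncol(pp))[cd$time_min == 300], grp[cd$time_min == 300]),
      function(i) lapply(splitRamanome(pp[, i], "replicate"), rsdProfile)
    )
    hc <- heterogeneityCompare(het, 782)
    summary$heterogeneity_782_p <- hc$p
  }
  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(summary)
}
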