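#' Run the full post-processing pipeline
#'
#' Executes every stage in order on a feature table: QC filtering,
#' molecular-descriptor computation, homolog-series detection, 5-year
#' binning, z-scoring and two-level Ward clustering, class and cluster
#' change-point / fold-change / trend inference, intensity-weighted
#' descriptor records over the biogenic subset (clusters 1A and 2), proxy
#' correlations against the anthropogenic cluster mean, and identification
#' confidence levels. Returns a machine-readable report; each stage logs a
#' row count.
#'
#' @param features an [NTSExperiment], or a [generatorConfig()] (the
#'   synthetic dataset is then generated internally and its proxies,
#'   standards, spectral library and MS2 spectra are used).
#' @param proxies named list of proxy `data.frame`s (`year`, `value`).
#' @param standards reference-standard table or NULL.
#' @param speclib spectral library from [readSpectralLibrary()] or NULL.
#' @param ms2 named list of per-molecule MS2 spectra or NULL.
#' @param filter a [filterSettings()].
#' @param descriptor a [descriptorConfig()].
#' @param binWidth,anchor binning grid (see [binIntensities()]).
#' @param minMembers homolog-series threshold (see [findHomologSeries()]).
#' @param figuresDir if non-NULL, Van Krevelen / Kroll scatters and the
#'   clustering heat map are written there as PNG files.
#' @param reportPath if non-NULL, the report is also written as JSON.
#' @param verbose print stage logs (default TRUE).
#' @return a named list report (see Details) with the configuration hash in
#'   `$configHash`.
#' @export
runPipeline <- function(features, proxies = list(), standards = NULL,
                        speclib = NULL, ms2 = NULL,
                        filter = filterSettings(),
                        descriptor = descriptorConfig(),
                        binWidth = 5, anchor = 1800, minMembers = 3,
                        figuresDir = NULL, reportPath = NULL,
                        verbose = TRUE) {
  log <- function(...) if (verbose) message(sprintf(...))
  truth <- NULL
  if (inherits(features, "GeneratorConfig")) {
    sim <- simulateIceCore(features)
    features <- sim$features; proxies <- sim$proxies
    standards <- sim$standards; speclib <- sim$speclib; ms2 <- sim$ms2
    truth <- sim$truth
    log("simulate: %d profiles x %d samples", nrow(features), ncol(features))
  }
  stopifnot(is(features, "NTSExperiment"))
  cfgHash <- .configHash(list(filter = filter, descriptor = descriptor,
                              binWidth = binWidth, anchor = anchor,
                              minMembers = minMembers))

  ## filter
  flt <- applyQcFilters(features, filter)
  kept <- flt$kept
  log("filter: kept %d of %d profiles", nrow(kept), nrow(features))

  ## descriptors
  forms <- stats::setNames(formulas(kept), rownames(kept))
  desc <- computeDescriptors(forms, descriptor)
  log("descriptors: %d molecules, %.1f%% aromatic", nrow(desc),
      aromaticFraction(desc))

  ## homolog series
  series <- findHomologSeries(forms, minMembers = minMembers,
                              rt = rowData(kept)$rt)
  log("homologs: %d series, %d member molecules",
      length(unique(series$series_id)), nrow(series))

  ## binning
  binned <- binIntensities(kept, binWidth = binWidth, anchor = anchor)
  yrs <- binYears(binned)
  log("bin: %d bins of %g yr", length(yrs), binWidth)

  ## class series, change points, folds
  cs <- classSeries(binned, desc$compound_class)
  classCP <- list(); classFolds <- list()
  for (cl in rownames(cs$series)) {
    v <- cs$series[cl, ]
    if (sum(!is.na(v)) >= 4 && stats::sd(v, na.rm = TRUE) > 0) {
      cp <- detectChangePoint(v, yrs)
      classCP[[cl]] <- cp
      # a class absent before its change point has no defined fold (NA)
      classFolds[[cl]] <- suppressWarnings(foldChange(v, yrs, cp$year)$fold)
    }
  }

  ## clustering
  z <- zscoreRows(binned)
  clust <- clusterMolecules(z, binYears = yrs)
  labels <- clusterLabels(clust)
  summaries <- summarizeClusters(clust, desc)
  shares <- clusterShare(clust, binned)
  log("cluster: %s",
      paste(sprintf("%s n=%d", names(table(labels)), table(labels)),
            collapse = ", "))

  ## anthropogenic mean series, change point, trends
  zc <- z[names(labels), , drop = FALSE]
  anthroMean <- colMeans(zc[labels != "2", , drop = FALSE])
  anthroCP <- detectChangePoint(anthroMean, yrs)
  trends <- lapply(rownames(clusterMeanSeries(clust)), function(cl) {
    trendTest(clusterMeanSeries(clust)[cl, ], yrs)
  })
  names(trends) <- rownames(clusterMeanSeries(clust))

  ## weighted descriptor records over the biogenic subset (1A u 2)
  subset12 <- names(labels)[labels %in% c("1A", "2")]
  wfields <- c(oc_ratio = "oc_ratio", osc = "osc", nC = "nC", dbe = "dbe",
               chi_c = "chi_c")
  weighted <- lapply(wfields, function(f) {
    weightedDescriptor(binned, stats::setNames(desc[[f]], desc$id), subset12)
  })
  weightedCP <- lapply(weighted, function(w) {
    if (sum(!is.na(w$value)) >= 4 && stats::sd(w$value, na.rm = TRUE) > 0)
      detectChangePoint(w$value, w$year) else NULL
  })
  weightedWindows <- lapply(names(weighted), function(f) {
    cp <- weightedCP[[f]]
    cpYear <- if (is.null(cp)) stats::median(yrs) else cp$year
    list(cpYear = cpYear,
         pre = windowStats(weighted[[f]], min(yrs), cpYear),
         post = windowStats(weighted[[f]], cpYear, max(yrs) + binWidth))
  })
  names(weightedWindows) <- names(weighted)

  ## group contrast: 1A vs 2 oxidation
  contrast <- list(
    oc = compareGroups(desc$oc_ratio[desc$id %in% names(labels)[labels == "1A"]],
                       desc$oc_ratio[desc$id %in% names(labels)[labels == "2"]]),
    osc = compareGroups(desc$osc[desc$id %in% names(labels)[labels == "1A"]],
                        desc$osc[desc$id %in% names(labels)[labels == "2"]]))

  ## proxy correlations vs the anthropogenic cluster mean
  proxyCor <- lapply(proxies, function(p) {
    tryCatch(proxyCorrelation(anthroMean, yrs, p), error = function(e) NA_real_)
  })

  ## identification levels
  idLevels <- NULL
  if (!is.null(standards) || !is.null(speclib)) {
    rd <- rowData(kept)
    lv <- vapply(rownames(kept), function(id) {
      assignLevel(list(formula = rd[id, "formula"], rt = rd[id, "rt"],
                       ms2 = if (!is.null(ms2)) ms2[[id]] else NULL),
                  standards, speclib)$level
    }, integer(1))
    idLevels <- table(factor(lv, levels = 1:5))
    log("identify: levels %s", paste(sprintf("L%d=%d", 1:5, idLevels),
                                     collapse = " "))
  }

  ## region tallies
  krollTally <- table(unlist(desc$kroll_regions))
  vkTally <- table(desc$vk_region)

  report <- list(
    configHash = cfgHash,
    nInput = nrow(features), nKept = nrow(kept), filterTally = flt$tally,
    classCounts = table(factor(desc$compound_class,
                               levels = c("CHO", "CHNO", "CHNOS", "CHOS",
                                          "other"))),
    recordShare = cs$recordShare,
    aromaticFraction = aromaticFraction(desc),
    vkTally = vkTally, krollTally = krollTally,
    homologSeries = series,
    binYears = yrs,
    classChangePoints = classCP, classFolds = classFolds,
    clusterLabels = labels, clusterSummaries = summaries,
    clusterShares = shares, clusterTrends = trends,
    anthroChangePoint = anthroCP,
    weighted = weighted, weightedChangePoints = weightedCP,
    weightedWindows = weightedWindows,
    oxidationContrast = contrast,
    proxyCorrelations = proxyCor,
    identificationLevels = idLevels,
    truth = truth)

  if (!is.null(figuresDir)) {
    dir.create(figuresDir, recursive = TRUE, showWarnings = FALSE)
    .savePlot(plotVanKrevelen(desc), file.path(figuresDir, "van_krevelen.png"))
    .savePlot(plotKroll(desc), file.path(figuresDir, "kroll.png"))
    plotClusterHeatmap(z, clust,
                       file = file.path(figuresDir, "clustergram.png"))
  }
  if (!is.null(reportPath)) writeReport(report, reportPath)
  report
}

.configHash <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(x, tf)
  unname(tools::md5sum(tf))
}

.savePlot <- function(p, path, width = 6, height = 5) {
  grDevices::png(path, width = width * 100, height = height * 100, res = 110)
  print(p)
  grDevices::dev.off()
  invisible(path)
}

#' Write a pipeline report as JSON
#'
#' Serialises the scalar and tabular parts of a [runPipeline()] report
#' (tables become arrays of rows; the clustering tree is omitted).
#'
#' @param report a [runPipeline()] report.
#' @param path output JSON path.
#' @return invisibly, the path.
#' @export
writeReport <- function(report, path) {
  out <- report
  out$truth <- NULL
  out$clusterSummaries <- lapply(report$clusterSummaries, function(s) {
    list(n = s$n, classCounts = as.list(s$classCounts),
         descriptors = as.data.frame(s$descriptors))
  })
  for (f in c("classCounts", "filterTally", "vkTally", "krollTally",
              "identificationLevels"))
    if (!is.null(out[[f]])) out[[f]] <- as.list(out[[f]])
  out$clusterLabels <- as.list(out$clusterLabels)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, na = "null")
  invisible(path)
}
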