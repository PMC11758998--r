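#' Row-wise z-score standardisation
#'
#' Standardises each molecule's binned series to mean 0, SD 1 (sample SD,
#' n - 1 denominator). Degenerate rows (SD = 0, or fewer than 2 non-missing
#' bins) become all-zero and are flagged in the `degenerate` attribute.
#' Missing bins stay missing.
#'
#' @param binned a [BinnedIntensities] or a molecules x bins matrix.
#' @return matrix of z-scores with attribute `degenerate` (logical vector).
#' @export
zscoreRows <- function(binned) {
  m <- if (is(binned, "BinnedIntensities")) binMatrix(binned) else binned
  if (ncol(m) < 2) stop("z-scoring needs at least 2 bins")
  mu <- rowMeans(m, na.rm = TRUE)
  sd <- apply(m, 1, stats::sd, na.rm = TRUE)
  deg <- !is.finite(sd) | sd == 0
  z <- (m - mu) / ifelse(deg, 1, sd)
  z[deg, ] <- 0
  attr(z, "degenerate") <- deg
  z
}

#' Two-level Ward clustering of molecule time series
#'
#' Reproduces the clustergram workflow: agglomerative hierarchical
#' clustering of z-scored molecule series with Euclidean distance and Ward
#' linkage (`ward.D2`, the Ward criterion on Euclidean distances), cut at
#' k = 2 into a natural and an anthropogenic cluster, with the
#' anthropogenic branch subdivided again at k = 2 into 1A (biogenic +
#' anthropogenic, present throughout) and 1B (purely anthropogenic, absent
#' early in the record).
#'
#' The anthropogenic branch is identified proxy-free as the top-level
#' cluster whose mean z-score series correlates more positively with a
#' monotone ramp over the bins. Within it, 1B is the subcluster with the
#' lower mean z-score over the first half of the record (purely industrial
#' molecules sit far below their own mean before onset). Degenerate
#' (constant) rows are excluded from clustering and reported separately.
#'
#' @param z z-score matrix from [zscoreRows()] (rows named by molecule id).
#' @param binYears optional bin start-years for the mean-series columns.
#' @return a [MoleculeClustering].
#' @export
clusterMolecules <- function(z, binYears = NULL) {
  deg <- attr(z, "degenerate")
  if (is.null(deg)) deg <- rep(FALSE, nrow(z))
  if (is.null(rownames(z)))
    rownames(z) <- sprintf("M%04d", seq_len(nrow(z)))
  excluded <- rownames(z)[deg]
  zz <- z[!deg, , drop = FALSE]
  if (nrow(zz) < 3) stop("clustering needs at least 3 non-degenerate molecules")
  zz[is.na(zz)] <- 0
  if (is.null(binYears)) binYears <- seq_len(ncol(zz))

  tree <- stats::hclust(stats::dist(zz), method = "ward.D2")
  top <- stats::cutree(tree, k = 2)

  ramp <- seq_len(ncol(zz))
  rampCor <- vapply(1:2, function(k) {
    stats::cor(colMeans(zz[top == k, , drop = FALSE]), ramp)
  }, numeric(1))
  anthro <- which.max(rampCor)

  labels <- ifelse(top == anthro, "1", "2")
  names(labels) <- rownames(zz)

  aRows <- zz[labels == "1", , drop = FALSE]
  if (nrow(aRows) >= 2) {
    sub <- if (nrow(aRows) == 2) {
      stats::setNames(1:2, rownames(aRows))
    } else {
      subTree <- stats::hclust(stats::dist(aRows), method = "ward.D2")
      stats::cutree(subTree, k = 2)
    }
    firstHalf <- seq_len(floor(ncol(zz) / 2))
    earlyMean <- vapply(1:2, function(k) {
      mean(aRows[sub == k, firstHalf, drop = FALSE])
    }, numeric(1))
    bIdx <- which.min(earlyMean)
    labels[names(sub)] <- ifelse(sub == bIdx, "1B", "1A")
  } else {
    labels[labels == "1"] <- "1A"
  }

  lev <- intersect(c("1A", "1B", "2"), unique(labels))
  meanSeries <- do.call(rbind, lapply(lev, function(cl) {
    colMeans(zz[labels == cl, , drop = FALSE])
  }))
  dimnames(meanSeries) <- list(lev, colnames(zz))

  new("MoleculeClustering", tree = tree, labels = labels,
      meanSeries = meanSeries, binYears = as.numeric(binYears),
      excluded = excluded)
}

#' Per-cluster composition and descriptor summaries
#'
#' For each cluster: member count, compound-class tally, and unweighted
#' mean +/- SD of O/C, carbon oxidation state, DBE, aromaticity equivalent
#' and carbon number over members.
#'
#' @param clustering a [MoleculeClustering].
#' @param descriptors descriptor table from [computeDescriptors()] with ids
#'   matching the clustered molecules.
#' @return named list of per-cluster summaries, each with `n`,
#'   `classCounts` and `descriptors` (matrix with mean/sd rows).
#' @export
summarizeClusters <- function(clustering, descriptors) {
  labels <- clusterLabels(clustering)
  idx <- match(names(labels), descriptors$id)
  if (anyNA(idx)) stop("descriptors missing for some clustered molecules")
  fields <- c(oc_ratio = "oc_ratio", osc = "osc", dbe = "dbe",
              chi_c = "chi_c", nC = "nC")
  lapply(split(idx, labels), function(rows) {
    d <- descriptors[rows, , drop = FALSE]
    stats <- vapply(fields, function(f) {
      c(mean = mean(d[[f]]), sd = stats::sd(d[[f]]))
    }, numeric(2))
    list(n = nrow(d),
         classCounts = table(factor(d$compound_class,
                                    levels = c("CHO", "CHNO", "CHNOS",
                                               "CHOS", "other"))),
         descriptors = stats)
  })
}

#' Per-bin relative intensity share of each cluster
#'
#' For every bin, the summed intensity of a cluster's members divided by the
#' summed intensity of all labelled molecules (percent). Shares sum to 100
#' per bin.
#'
#' @param clustering a [MoleculeClustering].
#' @param binned the [BinnedIntensities] the clustering was computed from.
#' @return cluster x bins matrix of percent shares.
#' @export
clusterShare <- function(clustering, binned) {
  labels <- clusterLabels(clustering)
  m <- binMatrix(binned)[names(labels), , drop = FALSE]
  lev <- rownames(clusterMeanSeries(clustering))
  tot <- colSums(m)
  out <- do.call(rbind, lapply(lev, function(cl) {
    100 * colSums(m[labels == cl, , drop = FALSE]) / tot
  }))
  dimnames(out) <- list(lev, colnames(m))
  out
}
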