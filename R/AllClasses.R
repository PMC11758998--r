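#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData
#'   colData rowData<- colData<-
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' NTSExperiment: a nontarget-screening feature table
#'
#' Thin extension of [SummarizedExperiment::SummarizedExperiment] holding one
#' `intensity` assay (molecules x samples), per-molecule metadata in
#' `rowData` (`mz`, `rt`, `formula`, `peak_rating`, `group_cv`,
#' `is_background`, `blank_max`) and per-sample metadata in `colData`
#' (`depth_m`, `year_ce`, `enrichment_factor`). Missing formulas are `NA`.
#'
#' @slot .. inherits all slots from SummarizedExperiment.
#' @export
setClass("NTSExperiment", contains = "SummarizedExperiment")

setValidity("NTSExperiment", function(object) {
  msg <- character(0)
  if (!"intensity" %in% names(assays(object)))
    msg <- c(msg, "assay 'intensity' is required")
  else if (any(assay(object, "intensity") < 0, na.rm = TRUE))
    msg <- c(msg, "intensities must be >= 0")
  rd <- rowData(object)
  for (col in c("mz", "rt", "formula"))
    if (!col %in% colnames(rd)) msg <- c(msg, sprintf("rowData lacks '%s'", col))
  if (!"year_ce" %in% colnames(colData(object)))
    msg <- c(msg, "colData lacks 'year_ce'")
  if (length(msg)) msg else TRUE
})

#' Construct an NTSExperiment
#'
#' @param intensity numeric matrix, molecules x samples, non-negative.
#' @param rowData `data.frame`/`DataFrame` of per-molecule metadata; must
#'   contain `mz`, `rt` and `formula` (use `NA` for unassigned formulas).
#' @param colData per-sample metadata containing at least `year_ce`.
#' @param metadata optional list of experiment-level metadata.
#' @return an `NTSExperiment`.
#' @export
NTSExperiment <- function(intensity, rowData, colData, metadata = list()) {
  se <- SummarizedExperiment(
    assays = list(intensity = as.matrix(intensity)),
    rowData = DataFrame(rowData), colData = DataFrame(colData),
    metadata = metadata)
  new("NTSExperiment", se)
}

#' @describeIn NTSExperiment assigned molecular formulas (NA when absent)
#' @param x an `NTSExperiment`.
#' @export
formulas <- function(x) as.character(rowData(x)$formula)

#' @describeIn NTSExperiment assigned calendar years of the samples (CE)
#' @export
sampleYears <- function(x) as.numeric(colData(x)$year_ce)

#' @describeIn NTSExperiment the intensity assay matrix
#' @export
intensityMatrix <- function(x) assay(x, "intensity")

#' @describeIn NTSExperiment replace the intensity assay matrix
#' @param value replacement intensity matrix.
#' @export
`intensityMatrix<-` <- function(x, value) {
  SummarizedExperiment::assay(x, "intensity") <- value
  x
}

#' Re-exported SummarizedExperiment accessors
#'
#' `rowData()`, `colData()` and `assay()` (and their replacement forms) are
#' re-exported so feature and sample metadata can be inspected without
#' attaching SummarizedExperiment.
#'
#' @name reexports
#' @importFrom SummarizedExperiment assay<-
#' @export rowData colData assay
#' @export rowData<- colData<- assay<-
#' @aliases rowData colData assay rowData<- colData<- assay<-
NULL

setMethod("show", "NTSExperiment", function(object) {
  cat(sprintf("NTSExperiment: %d molecular profiles x %d samples\n",
              nrow(object), ncol(object)))
  yrs <- suppressWarnings(range(sampleYears(object), na.rm = TRUE))
  if (all(is.finite(yrs)))
    cat(sprintf("  record span: %.0f-%.0f CE\n", yrs[1], yrs[2]))
  nf <- sum(!is.na(rowData(object)$formula))
  cat(sprintf("  formulas assigned: %d/%d\n", nf, nrow(object)))
  invisible(NULL)
})

#' BinnedIntensities: molecules x time-bin mean intensities
#'
#' Per-molecule arithmetic means of sample intensities inside half-open
#' calendar bins `[start, start + width)`. Bins containing no sample are
#' `NA`, never 0.
#'
#' @slot matrix molecules x bins numeric matrix (NA = empty bin).
#' @slot binYears numeric, increasing bin start-years (CE).
#' @slot binWidth single numeric, bin width in years.
#' @slot sampleCount integer vector, samples per bin.
#' @export
setClass("BinnedIntensities", representation(
  matrix = "matrix", binYears = "numeric", binWidth = "numeric",
  sampleCount = "integer"))

setValidity("BinnedIntensities", function(object) {
  msg <- character(0)
  if (ncol(object@matrix) != length(object@binYears))
    msg <- c(msg, "matrix columns must match binYears")
  if (is.unsorted(object@binYears, strictly = TRUE))
    msg <- c(msg, "binYears must be strictly increasing")
  if (length(object@binWidth) != 1 || object@binWidth < 1)
    msg <- c(msg, "binWidth must be a single value >= 1")
  if (length(msg)) msg else TRUE
})

#' @describeIn BinnedIntensities bin start-years (CE)
#' @param x a `BinnedIntensities`.
#' @export
binYears <- function(x) x@binYears

#' @describeIn BinnedIntensities the molecules x bins matrix
#' @export
binMatrix <- function(x) x@matrix

setMethod("show", "BinnedIntensities", function(object) {
  cat(sprintf("BinnedIntensities: %d molecules x %d bins (width %g yr, %g-%g CE)\n",
              nrow(object@matrix), ncol(object@matrix), object@binWidth,
              min(object@binYears), max(object@binYears)))
  cat(sprintf("  empty bins: %d\n", sum(object@sampleCount == 0L)))
  invisible(NULL)
})

#' MoleculeClustering: hierarchical clustering of molecule time series
#'
#' Result of the two-level Ward clustering: the agglomerative tree, flat
#' labels (`1A`, `1B`, `2`), per-cluster mean z-score series, and the set of
#' degenerate (constant) molecules excluded from clustering.
#'
#' @slot tree the top-level `hclust` tree.
#' @slot labels named character vector, molecule id -> cluster label.
#' @slot meanSeries cluster x bins matrix of mean z-scores.
#' @slot binYears bin start-years matching `meanSeries` columns.
#' @slot excluded character, ids of constant rows left out of the clustering.
#' @export
setClass("MoleculeClustering", representation(
  tree = "ANY", labels = "character", meanSeries = "matrix",
  binYears = "numeric", excluded = "character"))

setValidity("MoleculeClustering", function(object) {
  msg <- character(0)
  if (is.null(names(object@labels)))
    msg <- c(msg, "labels must be named by molecule id")
  if (!all(object@labels %in% c("1A", "1B", "2")))
    msg <- c(msg, "labels must be one of 1A, 1B, 2")
  if (length(msg)) msg else TRUE
})

#' @describeIn MoleculeClustering molecule-to-cluster label vector
#' @param x a `MoleculeClustering`.
#' @export
clusterLabels <- function(x) x@labels

#' @describeIn MoleculeClustering per-cluster mean z-score series
#' @export
clusterMeanSeries <- function(x) x@meanSeries

setMethod("show", "MoleculeClustering", function(object) {
  tab <- table(object@labels)
  cat("MoleculeClustering:",
      paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  if (length(object@excluded))
    cat(sprintf("  excluded constant rows: %d\n", length(object@excluded)))
  invisible(NULL)
})
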