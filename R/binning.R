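#' Bin sample intensities into multi-year means
#'
#' Averages the per-molecule sample intensities into half-open calendar bins
#' `[start, start + width)` anchored at `anchor` (default 1800 CE), smoothing
#' year-to-year variability of atmospheric transport and snow preservation.
#' A sample dated exactly on a boundary belongs to the bin starting there.
#' Bins containing no sample are `NA`, never 0.
#'
#' @param x an [NTSExperiment] with dated samples.
#' @param binWidth bin width in years (default 5).
#' @param anchor start year of the binning grid (default 1800).
#' @return a [BinnedIntensities].
#' @export
binIntensities <- function(x, binWidth = 5, anchor = 1800) {
  stopifnot(is(x, "NTSExperiment"), binWidth >= 1)
  years <- sampleYears(x)
  if (!length(years) || all(is.na(years))) stop("no dated samples")
  starts <- anchor + floor((years - anchor) / binWidth) * binWidth
  grid <- seq(min(starts), max(starts), by = binWidth)
  im <- intensityMatrix(x)
  mat <- matrix(NA_real_, nrow(im), length(grid),
                dimnames = list(rownames(im), grid))
  counts <- integer(length(grid))
  for (j in seq_along(grid)) {
    sel <- which(starts == grid[j])
    counts[j] <- length(sel)
    if (length(sel))
      mat[, j] <- rowMeans(im[, sel, drop = FALSE])
  }
  new("BinnedIntensities", matrix = mat, binYears = as.numeric(grid),
      binWidth = binWidth, sampleCount = counts)
}

#' Per-class aggregated intensity series
#'
#' Sums molecule intensities within each compound class per bin, and reports
#' each class's share of the record-total intensity (percent). Shares per
#' bin form a probability vector.
#'
#' @param binned a [BinnedIntensities].
#' @param classes character vector of class labels parallel to the binned
#'   rows (e.g. `descriptors$compound_class`).
#' @return list with `series` (class x bins summed-intensity matrix),
#'   `share` (class x bins percent shares) and `recordShare` (named percent
#'   share of the record-total intensity per class).
#' @export
classSeries <- function(binned, classes) {
  m <- binMatrix(binned)
  stopifnot(length(classes) == nrow(m))
  lev <- unique(classes)
  series <- do.call(rbind, lapply(lev, function(cl) {
    colSums(m[classes == cl, , drop = FALSE])
  }))
  dimnames(series) <- list(lev, colnames(m))
  tot <- colSums(series)
  share <- sweep(series, 2, tot, "/") * 100
  grand <- rowSums(series, na.rm = TRUE)
  list(series = series, share = share,
       recordShare = 100 * grand / sum(grand))
}

#' Intensity-weighted descriptor series
#'
#' Per bin, the intensity-weighted mean of a per-molecule descriptor over a
#' molecule subset: sum(I_i * x_i) / sum(I_i) over subset molecules with
#' positive intensity in that bin. Used for the weighted O/C, carbon
#' oxidation state, carbon number, DBE and aromaticity records; to track
#' atmospheric oxidation the purely anthropogenic molecules (cluster 1B) are
#' typically excluded, i.e. `subset` = clusters 1A and 2.
#'
#' @param binned a [BinnedIntensities].
#' @param values named numeric vector of the descriptor (names = molecule
#'   ids) or a vector parallel to the binned rows.
#' @param subset optional character vector of molecule ids to restrict to.
#' @return `data.frame` with `year` (bin start) and `value` (NA when the bin
#'   has zero total weight).
#' @export
weightedDescriptor <- function(binned, values, subset = NULL) {
  m <- binMatrix(binned)
  if (!is.null(names(values))) {
    miss <- setdiff(rownames(m), names(values))
    if (length(miss)) stop("descriptor values missing for some molecules")
    values <- values[rownames(m)]
  } else stopifnot(length(values) == nrow(m))
  if (!is.null(subset)) {
    sel <- rownames(m) %in% subset
    m <- m[sel, , drop = FALSE]
    values <- values[sel]
  }
  w <- m
  w[is.na(w)] <- 0
  num <- colSums(w * values)
  den <- colSums(w)
  val <- ifelse(den > 0, num / den, NA_real_)
  data.frame(year = binYears(binned), value = unname(val))
}

#' Windowed mean and spread of a descriptor series
#'
#' Mean +/- SD of a weighted-descriptor series over a year window; the
#' spread is the standard deviation across bins within the window.
#'
#' @param series `data.frame` from [weightedDescriptor()].
#' @param from,to inclusive start / exclusive end of the window (bin start
#'   years).
#' @return named numeric `c(mean, sd, n)`.
#' @export
windowStats <- function(series, from, to) {
  sel <- series$year >= from & series$year < to & !is.na(series$value)
  v <- series$value[sel]
  c(mean = mean(v), sd = stats::sd(v), n = length(v))
}
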