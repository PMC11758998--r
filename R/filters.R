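#' Quality-control filter settings
#'
#' The six predicates applied after vendor preprocessing, in fixed order:
#' (i) not flagged as background, (ii) peak rating at least
#' `minPeakRating`, (iii) replicate group CV at most `maxGroupCV` percent,
#' (iv) molecular formula assigned, (v) maximum sample intensity at least
#' `minMaxIntensity`, (vi) maximum sample intensity over maximum blank
#' intensity at least `minSampleBlankRatio` (an all-zero blank passes: the
#' ratio is infinite).
#'
#' @param minPeakRating minimum vendor peak rating (default 7.0).
#' @param maxGroupCV maximum group coefficient of variation, percent (15).
#' @param minMaxIntensity minimum of the per-profile maximum intensity (5e6).
#' @param minSampleBlankRatio minimum sample-to-blank intensity ratio (3).
#' @param requireFormula drop profiles without an assigned formula (TRUE).
#' @param excludeBackground drop profiles flagged as background (TRUE).
#' @return list with class `FilterSettings`.
#' @export
filterSettings <- function(minPeakRating = 7.0, maxGroupCV = 15,
                           minMaxIntensity = 5e6, minSampleBlankRatio = 3,
                           requireFormula = TRUE, excludeBackground = TRUE) {
  structure(list(minPeakRating = minPeakRating, maxGroupCV = maxGroupCV,
                 minMaxIntensity = minMaxIntensity,
                 minSampleBlankRatio = minSampleBlankRatio,
                 requireFormula = requireFormula,
                 excludeBackground = excludeBackground),
            class = "FilterSettings")
}

#' Apply the six-predicate QC filter
#'
#' A profile is kept iff all predicates pass. Rejections are tallied by the
#' first failing predicate in the order (i) background, (ii) rating,
#' (iii) cv, (iv) formula, (v) intensity, (vi) blank, so the tally plus the
#' kept count always equals the input count.
#'
#' @param x an [NTSExperiment].
#' @param settings a [filterSettings()].
#' @return list with `kept` (filtered `NTSExperiment`) and `tally` (named
#'   integer vector over the six predicates).
#' @export
applyQcFilters <- function(x, settings = filterSettings()) {
  stopifnot(is(x, "NTSExperiment"))
  rd <- rowData(x)
  im <- intensityMatrix(x)
  maxI <- apply(im, 1, max)
  blankMax <- if ("blank_max" %in% colnames(rd)) rd$blank_max else
    rep(0, nrow(x))
  ratio <- ifelse(blankMax > 0, maxI / blankMax, Inf)

  pass <- cbind(
    background = if (settings$excludeBackground) !rd$is_background else TRUE,
    rating     = rd$peak_rating >= settings$minPeakRating,
    cv         = rd$group_cv <= settings$maxGroupCV,
    formula    = if (settings$requireFormula) !is.na(rd$formula) else TRUE,
    intensity  = maxI >= settings$minMaxIntensity,
    blank      = ratio >= settings$minSampleBlankRatio)
  keep <- rowSums(pass) == ncol(pass)

  firstFail <- apply(pass, 1, function(p) {
    w <- which(!p); if (length(w)) colnames(pass)[w[1]] else NA_character_
  })
  tally <- table(factor(firstFail[!keep], levels = colnames(pass)))
  list(kept = x[keep, ], tally = structure(as.integer(tally),
                                           names = colnames(pass)))
}

#' Recompute a group coefficient of variation
#'
#' Helper for feature tables that ship replicate intensity columns instead
#' of a vendor-computed CV: returns 100 * sd / mean per row.
#'
#' @param replicates numeric matrix, profiles x replicate injections.
#' @return numeric vector of CVs in percent (NA when the mean is 0).
#' @export
recomputeGroupCV <- function(replicates) {
  m <- rowMeans(replicates)
  s <- apply(replicates, 1, stats::sd)
  ifelse(m > 0, 100 * s / m, NA_real_)
}
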