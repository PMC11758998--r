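#' Detect an abrupt mean shift in a binned series
#'
#' Exhaustively evaluates every split of the series into two contiguous
#' segments and returns the split minimising the total within-segment sum of
#' squared deviations from the segment means (the single-change-point
#' residual-error criterion of standard mean-shift detectors). Implemented
#' via cumulative sums, so the scan is O(n); missing bins are dropped before
#' scanning. The change-point year is the start year of the first
#' post-change bin. `sseDrop` is the unsplit SSE minus the best split SSE; a
#' constant series yields `sseDrop` 0 and is flagged not significant.
#'
#' @param values numeric series (NA = missing bin).
#' @param years bin start-years parallel to `values`.
#' @return list with `year`, `index` (position in the non-missing series of
#'   the first post-change point), `sseDrop`, and `significant` (TRUE when
#'   the split reduces the SSE at all).
#' @export
detectChangePoint <- function(values, years = seq_along(values)) {
  stopifnot(length(values) == length(years))
  ok <- !is.na(values)
  v <- values[ok]; yr <- years[ok]
  n <- length(v)
  if (n < 4) stop("change-point detection needs at least 4 non-missing bins")
  cs <- cumsum(v); cs2 <- cumsum(v^2)
  tot <- cs[n]; tot2 <- cs2[n]
  j <- seq_len(n - 1)                      # left segment = 1..j
  sseL <- cs2[j] - cs[j]^2 / j
  sseR <- (tot2 - cs2[j]) - (tot - cs[j])^2 / (n - j)
  sse <- sseL + sseR
  best <- which.min(sse)
  sse0 <- tot2 - tot^2 / n
  drop <- sse0 - sse[best]
  list(year = yr[best + 1L], index = best + 1L, sseDrop = drop,
       significant = drop > sqrt(.Machine$double.eps) * max(1, sse0))
}

#' Fold change across a change point
#'
#' Ratio of the mean over the post-change bins to the mean over the
#' pre-change bins. Windows default to (record start, change point) and
#' (change point, record end).
#'
#' @param values numeric series (NA allowed).
#' @param years bin start-years parallel to `values`.
#' @param cpYear change-point year (first post-change bin start).
#' @return list with `fold` (NA with a warning when the pre-change mean is
#'   0), `preMean`, `postMean`.
#' @export
foldChange <- function(values, years, cpYear) {
  stopifnot(cpYear > min(years), cpYear <= max(years))
  pre <- mean(values[years < cpYear], na.rm = TRUE)
  post <- mean(values[years >= cpYear], na.rm = TRUE)
  if (!is.finite(pre) || pre == 0) {
    warning("undefined fold change: pre-change mean is zero")
    return(list(fold = NA_real_, preMean = pre, postMean = post))
  }
  list(fold = post / pre, preMean = pre, postMean = post)
}

#' Linear trend test
#'
#' Ordinary least squares of the series on the bin year; the slope's
#' two-sided p-value comes from the t-distribution with n - 2 degrees of
#' freedom. Significance is assessed at 0.05.
#'
#' @param values numeric series (NA allowed).
#' @param years bin start-years parallel to `values`.
#' @return list with `slope`, `pValue` (NA when the residual variance is
#'   degenerate), `significant`.
#' @export
trendTest <- function(values, years = seq_along(values)) {
  ok <- !is.na(values)
  v <- values[ok]; yr <- years[ok]
  if (length(v) < 3) stop("trend test needs at least 3 non-missing bins")
  if (stats::sd(yr) == 0) stop("degenerate year axis")
  if (stats::sd(v) == 0) {
    # constant series: zero slope, residual variance degenerate
    return(list(slope = 0, pValue = NA_real_, significant = FALSE))
  }
  fit <- stats::lm(v ~ yr)
  sm <- suppressWarnings(summary(fit))   # exact lines trip a perfect-fit note
  slope <- unname(sm$coefficients["yr", "Estimate"])
  p <- if (sm$sigma == 0) 0 else unname(sm$coefficients["yr", "Pr(>|t|)"])
  list(slope = slope, pValue = p,
       significant = is.finite(p) && p < 0.05)
}

#' Pearson correlation with a co-registered proxy series
#'
#' The proxy is linearly interpolated onto the series' bin years (matching
#' the ice-core alignment convention) and the Pearson correlation is taken
#' over the paired non-missing values.
#'
#' @param values numeric series on the ice-core bins (NA allowed).
#' @param years bin start-years parallel to `values`.
#' @param proxy `data.frame` with `year` and `value` (see [readProxy()]).
#' @return Pearson r.
#' @export
proxyCorrelation <- function(values, years, proxy) {
  stopifnot(all(c("year", "value") %in% names(proxy)))
  interp <- stats::approx(proxy$year, proxy$value, xout = years,
                          rule = 1)$y
  ok <- !is.na(values) & !is.na(interp)
  if (sum(ok) < 3) stop("fewer than 3 overlapping bins with the proxy")
  stats::cor(values[ok], interp[ok])
}

#' Compare a descriptor between two molecule groups
#'
#' Welch (unequal-variance) two-sided t-test on per-molecule descriptor
#' values, e.g. O/C or carbon oxidation state between clusters.
#'
#' @param a,b numeric vectors of per-molecule descriptor values.
#' @return list with `pValue`, `meanA`, `meanB`.
#' @export
compareGroups <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2) stop("both groups need >= 2 values")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    # degenerate: identical constants give p = 1, different constants p = 0
    return(list(pValue = if (mean(a) == mean(b)) 1 else 0,
                meanA = mean(a), meanB = mean(b), degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(pValue = tt$p.value, meanA = mean(a), meanB = mean(b),
       degenerate = FALSE)
}
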