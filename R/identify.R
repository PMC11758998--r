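#' Read a reference-standard table
#'
#' Delimited text with columns `name`, `formula` and `rt_min` (retention
#' time of the authentic standard on the same chromatographic method).
#'
#' @param path delimited text file.
#' @return `data.frame`.
#' @export
readReferenceStandards <- function(path) {
  df <- .readDelim(path)
  need <- c("name", "formula", "rt_min")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("standards table missing column(s): ", paste(miss, collapse = ", "))
  if (any(df$rt_min < 0)) stop("rt_min must be >= 0")
  df
}

#' Read an MSP-format spectral library
#'
#' Minimal parser for the NIST MSP text convention: records separated by
#' blank lines, `Name:` / `Formula:` headers, `Num Peaks:` followed by
#' whitespace- or semicolon-separated m/z intensity pairs. Peak intensities
#' are normalised to a base peak of 100 and peaks sorted by m/z.
#'
#' @param path MSP text file.
#' @return list of entries, each a list with `name`, `formula` and `peaks`
#'   (two-column matrix `mz`, `intensity`).
#' @export
readSpectralLibrary <- function(path) {
  lines <- readLines(path)
  entries <- list()
  cur <- NULL
  peaksLeft <- 0L
  flush <- function(cur) {
    if (is.null(cur) || !nrow(cur$peaks)) return(NULL)
    p <- cur$peaks[order(cur$peaks[, 1]), , drop = FALSE]
    p[, 2] <- 100 * p[, 2] / max(p[, 2])
    colnames(p) <- c("mz", "intensity")
    list(name = cur$name, formula = cur$formula, peaks = p)
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (!nzchar(ln)) {
      e <- flush(cur)
      if (!is.null(e)) entries[[length(entries) + 1L]] <- e
      cur <- NULL; peaksLeft <- 0L
      next
    }
    if (grepl("^(NAME|Name)\\s*:", ln)) {
      cur <- list(name = trimws(sub("^[^:]*:", "", ln)),
                  formula = NA_character_,
                  peaks = matrix(numeric(0), 0, 2))
    } else if (grepl("^(FORMULA|Formula)\\s*:", ln)) {
      cur$formula <- trimws(sub("^[^:]*:", "", ln))
    } else if (grepl("^Num [Pp]eaks\\s*:", ln)) {
      peaksLeft <- as.integer(trimws(sub("^[^:]*:", "", ln)))
    } else if (peaksLeft > 0L && grepl("^[0-9]", ln)) {
      toks <- as.numeric(strsplit(ln, "[;[:space:]]+")[[1]])
      toks <- toks[!is.na(toks)]
      pairs <- matrix(toks, ncol = 2, byrow = TRUE)
      cur$peaks <- rbind(cur$peaks, pairs)
      peaksLeft <- peaksLeft - nrow(pairs)
    }
  }
  e <- flush(cur)
  if (!is.null(e)) entries[[length(entries) + 1L]] <- e
  entries
}

#' Cosine similarity between two fragmentation spectra
#'
#' Greedy peak pairing within an m/z tolerance (closest pairs first), then
#' the cosine similarity of square-root-scaled intensities over the union of
#' matched and unmatched peaks. Symmetric in its arguments; identical
#' spectra score 1, spectra with disjoint m/z sets score 0.
#'
#' @param a,b two-column matrices (`mz`, `intensity`), non-empty.
#' @param mzTol m/z pairing tolerance in Da (default 0.01, Orbitrap-class).
#' @return score in \[0, 1\].
#' @export
spectralMatch <- function(a, b, mzTol = 0.01) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!nrow(a) || !nrow(b)) stop("spectra must be non-empty")
  # all candidate pairs within tolerance, closest Delta-m/z first
  cand <- which(abs(outer(a[, 1], b[, 1], "-")) <= mzTol, arr.ind = TRUE)
  if (nrow(cand)) {
    dmz <- abs(a[cand[, 1], 1] - b[cand[, 2], 1])
    cand <- cand[order(dmz), , drop = FALSE]
  }
  usedA <- logical(nrow(a)); usedB <- logical(nrow(b))
  va <- numeric(0); vb <- numeric(0)
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]
    if (usedA[i] || usedB[j]) next
    usedA[i] <- TRUE; usedB[j] <- TRUE
    va <- c(va, sqrt(a[i, 2])); vb <- c(vb, sqrt(b[j, 2]))
  }
  va <- c(va, sqrt(a[!usedA, 2]), rep(0, sum(!usedB)))
  vb <- c(vb, rep(0, sum(!usedA)), sqrt(b[!usedB, 2]))
  denom <- sqrt(sum(va^2)) * sqrt(sum(vb^2))
  if (denom == 0) return(0)
  sum(va * vb) / denom
}

#' Assign an identification confidence level
#'
#' Five-tier confidence scale for mass-spectrometric identification:
#' \itemize{
#'   \item level 5 — exact mass only (no molecular formula);
#'   \item level 4 — unequivocal molecular formula, no structural evidence;
#'   \item level 3 — tentative candidates: two or more library spectra score
#'     at or above the match threshold;
#'   \item level 2 — probable structure: exactly one library spectrum scores
#'     at or above the threshold;
#'   \item level 1 — confirmed: a reference standard with the same formula
#'     matches within `rtTol` minutes of retention time.
#' }
#' A reference-standard match confirms level 1 on its own (the in-house
#' database route); added evidence never lowers the level.
#'
#' @param feature list with `formula` (string or NA), `rt` (minutes) and
#'   optionally `ms2` (two-column spectrum matrix).
#' @param standards reference-standard table from
#'   [readReferenceStandards()], or NULL.
#' @param library spectral library from [readSpectralLibrary()], or NULL.
#' @param threshold minimum library cosine score (default 0.6).
#' @param mzTol spectral m/z pairing tolerance in Da (default 0.01).
#' @param rtTol retention-time tolerance for standard confirmation in
#'   minutes (default 0.1).
#' @return list with `level` (integer 1-5), `candidates` (`data.frame` of
#'   name/score) and `evidence` (character rationale).
#' @export
assignLevel <- function(feature, standards = NULL, library = NULL,
                        threshold = 0.6, mzTol = 0.01, rtTol = 0.1) {
  noFormula <- is.null(feature$formula) || is.na(feature$formula) ||
    !nzchar(feature$formula)
  cand <- data.frame(name = character(0), score = numeric(0))
  if (noFormula)
    return(list(level = 5L, candidates = cand,
                evidence = "exact mass only; no molecular formula"))
  canon <- formatFormula(parseFormula(feature$formula))

  # reference-standard confirmation
  if (!is.null(standards) && nrow(standards) && !is.null(feature$rt)) {
    sameFormula <- vapply(standards$formula, function(f) {
      identical(formatFormula(parseFormula(f)), canon)
    }, logical(1))
    dRT <- abs(standards$rt_min - feature$rt)
    hit <- which(sameFormula & dRT <= rtTol)
    if (length(hit)) {
      hit <- hit[which.min(dRT[hit])]
      return(list(
        level = 1L,
        candidates = data.frame(name = standards$name[hit], score = 1),
        evidence = sprintf(
          "reference standard '%s' matches formula with |dRT| = %.3f min <= %.1f",
          standards$name[hit], dRT[hit], rtTol)))
    }
  }

  # spectral-library evidence
  if (!is.null(library) && length(library) && !is.null(feature$ms2) &&
      nrow(feature$ms2)) {
    scores <- vapply(library, function(e) {
      spectralMatch(feature$ms2, e$peaks, mzTol)
    }, numeric(1))
    nm <- vapply(library, `[[`, character(1), "name")
    keep <- scores >= threshold
    cand <- data.frame(name = nm[keep], score = scores[keep])
    cand <- cand[order(-cand$score), , drop = FALSE]
    if (nrow(cand) == 1)
      return(list(level = 2L, candidates = cand,
                  evidence = sprintf("unique library match '%s' (score %.2f)",
                                     cand$name[1], cand$score[1])))
    if (nrow(cand) >= 2)
      return(list(level = 3L, candidates = cand,
                  evidence = sprintf("%d library candidates above %.2f",
                                     nrow(cand), threshold)))
  }
  list(level = 4L, candidates = cand,
       evidence = "molecular formula only; no structural evidence")
}
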