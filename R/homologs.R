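#' Homolog-series key of a formula
#'
#' Two formulas belong to the same CH2-homolog series iff they share the
#' heteroatom counts (O, N, S) and the hydrogen offset k = H - 2C, i.e. they
#' differ only by an integer number of CH2 units. The series notation
#' CnH(2n+k)Oo follows: succinic acid C4H6O4 has k = -2, O4 (the
#' dicarboxylic series); pinic acid C9H14O4 has k = -4, O4. A constant DBE
#' within a key follows arithmetically.
#'
#' @param formulas character vector of formulas (carbon count must be > 0).
#' @return character vector of keys of the form `"k=-2|O4|N0|S0"` (rarer
#'   heteroatoms, e.g. halogens or P, are appended so that formulas
#'   differing in them never share a key).
#' @export
homologKey <- function(formulas) {
  vapply(formulas, function(f) {
    ct <- parseFormula(f)
    C <- if ("C" %in% names(ct)) ct[["C"]] else 0L
    H <- if ("H" %in% names(ct)) ct[["H"]] else 0L
    if (C <= 0) stop("homolog key requires carbon")
    get <- function(s) if (s %in% names(ct)) ct[[s]] else 0L
    rest <- ct[!names(ct) %in% c("C", "H", "N", "O", "S")]
    rest <- rest[rest > 0]
    extra <- if (length(rest))
      paste0("|", paste0(sort(names(rest)), rest[sort(names(rest))],
                         collapse = "|"))
    else ""
    sprintf("k=%d|O%d|N%d|S%d%s", H - 2L * C, get("O"), get("N"), get("S"),
            extra)
  }, character(1), USE.NAMES = FALSE)
}

#' Detect CH2 homolog series
#'
#' Groups formulas by [homologKey()] and returns every series with at least
#' `minMembers` distinct members, sorted by member count (descending) then
#' key. A formula belongs to exactly one series; duplicated formulas count
#' once. Gaps in the carbon-number ladder are allowed (observed series may
#' skip a chain length). Retention-time coherence, when `rt` is supplied, is
#' reported as a Spearman correlation diagnostic (`rt_trend`) but never
#' enforced.
#'
#' @param formulas character vector; names (if any) are kept as member ids.
#' @param minMembers minimum number of distinct members (default 3).
#' @param rt optional numeric retention times parallel to `formulas`.
#' @return `data.frame` with one row per member: `series_id`, `key`,
#'   `k_offset`, `O`, `N`, `S`, `formula`, `nC`, `dbe` (and `rt_trend` when
#'   `rt` is given); zero rows when no series qualifies.
#' @export
findHomologSeries <- function(formulas, minMembers = 3, rt = NULL) {
  stopifnot(minMembers >= 2)
  if (!length(formulas)) return(.emptySeries(!is.null(rt)))
  keys <- homologKey(formulas)
  ec <- elementCounts(formulas)
  d <- dbe(formulas)
  ids <- if (!is.null(names(formulas))) names(formulas) else
    as.character(seq_along(formulas))

  df <- data.frame(id = ids, key = keys, formula = unname(formulas),
                   nC = unname(ec[, "C"]), O = unname(ec[, "O"]),
                   N = unname(ec[, "N"]), S = unname(ec[, "S"]),
                   k_offset = as.integer(ec[, "H"] - 2 * ec[, "C"]),
                   dbe = d, stringsAsFactors = FALSE)
  if (!is.null(rt)) df$rt <- rt
  # distinct members only
  df <- df[!duplicated(df[, c("key", "formula")]), , drop = FALSE]

  sizes <- table(df$key)
  keep <- names(sizes)[sizes >= minMembers]
  if (!length(keep)) return(.emptySeries(!is.null(rt)))
  ord <- keep[order(-as.integer(sizes[keep]), keep)]

  out <- do.call(rbind, lapply(seq_along(ord), function(i) {
    g <- df[df$key == ord[i], , drop = FALSE]
    g <- g[order(g$nC), , drop = FALSE]
    g$series_id <- sprintf("S%03d", i)
    if (!is.null(rt)) {
      g$rt_trend <- if (nrow(g) >= 3 && stats::sd(g$rt) > 0)
        suppressWarnings(stats::cor(g$nC, g$rt, method = "spearman"))
      else NA_real_
    }
    g
  }))
  cols <- c("series_id", "key", "k_offset", "O", "N", "S", "formula",
            "nC", "dbe", if (!is.null(rt)) c("rt", "rt_trend"))
  rownames(out) <- NULL
  out[, cols]
}

.emptySeries <- function(withRt) {
  out <- data.frame(series_id = character(0), key = character(0),
                    k_offset = integer(0), O = integer(0), N = integer(0),
                    S = integer(0), formula = character(0), nC = numeric(0),
                    dbe = numeric(0), stringsAsFactors = FALSE)
  if (withRt) { out$rt <- numeric(0); out$rt_trend <- numeric(0) }
  out
}
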