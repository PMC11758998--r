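#' Parse a molecular formula in Hill notation
#'
#' Parses an elemental formula string such as \code{"C8H8O3"} into a named
#' integer vector of element counts. Element symbols are one capital letter
#' optionally followed by one lowercase letter; an omitted count means 1.
#' Unknown element symbols are kept as-is, so exotic heteroatoms survive a
#' parse/format round trip.
#'
#' @param text a single non-empty formula string.
#' @return named integer vector of element counts (names are element symbols,
#'   repeated symbols are summed).
#' @examples
#' parseFormula("C8H8O3")
#' parseFormula("C6H5NO3")
#' @export
parseFormula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) ||
      !nzchar(trimws(text))) {
    stop("formula must be a single non-empty string")
  }
  text <- trimws(text)
  n <- nchar(text)
  counts <- integer(0)
  i <- 1L
  while (i <= n) {
    ch <- substr(text, i, i)
    if (!grepl("^[A-Z]$", ch)) {
      stop(sprintf("malformed formula '%s': unexpected character '%s' at position %d",
                   text, ch, i))
    }
    sym <- ch
    i <- i + 1L
    if (i <= n && grepl("^[a-z]$", substr(text, i, i))) {
      sym <- paste0(sym, substr(text, i, i))
      i <- i + 1L
    }
    digits <- ""
    while (i <= n && grepl("^[0-9]$", substr(text, i, i))) {
      digits <- paste0(digits, substr(text, i, i))
      i <- i + 1L
    }
    cnt <- if (nzchar(digits)) as.integer(digits) else 1L
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + cnt
  }
  if (sum(counts) == 0L) stop(sprintf("formula '%s' has no atoms", text))
  counts
}

#' Serialize element counts in Hill order
#'
#' Hill convention: carbon first, hydrogen second, all other elements
#' alphabetically (if no carbon, everything alphabetical). Counts of 1 are
#' implicit; zero counts are dropped.
#'
#' @param counts named integer vector as returned by [parseFormula()].
#' @return formula string.
#' @export
formatFormula <- function(counts) {
  counts <- counts[counts > 0]
  syms <- names(counts)
  if ("C" %in% syms) {
    rest <- sort(setdiff(syms, c("C", "H")))
    ord <- c("C", intersect("H", syms), rest)
  } else {
    ord <- sort(syms)
  }
  paste0(vapply(ord, function(s) {
    if (counts[[s]] == 1L) s else paste0(s, counts[[s]])
  }, character(1)), collapse = "")
}

HALOGENS <- c("F", "Cl", "Br", "I")

.count <- function(counts, sym) {
  if (sym %in% names(counts)) as.numeric(counts[[sym]]) else 0
}

#' Element-count matrix for a set of formulas
#'
#' Vectorised helper: parses each formula and returns a matrix with one row
#' per formula and columns C, H, N, O, S, X (X = summed halogens F, Cl, Br, I)
#' plus `other` (count of atoms of any further element).
#'
#' @param formulas character vector of Hill-notation formulas.
#' @return numeric matrix with rownames taken from `formulas` names (if any).
#' @export
elementCounts <- function(formulas) {
  out <- t(vapply(formulas, function(f) {
    ct <- parseFormula(f)
    hal <- sum(vapply(HALOGENS, function(s) .count(ct, s), numeric(1)))
    oth <- sum(ct[!names(ct) %in% c("C", "H", "N", "O", "S", HALOGENS)])
    c(C = .count(ct, "C"), H = .count(ct, "H"), N = .count(ct, "N"),
      O = .count(ct, "O"), S = .count(ct, "S"), X = hal, other = oth)
  }, numeric(7)))
  rownames(out) <- names(formulas)
  out
}

#' Descriptor configuration
#'
#' Tunable constants of the aromaticity equivalent: `m` and `n` are the
#' fractions of oxygen and sulfur atoms assumed to sit in pi-bonded
#' structures (0.5 is appropriate for carboxylic acids and esters, the
#' compound families favoured by (-)ESI), and `aromaticThreshold` is the
#' value at or above which a molecule is flagged aromatic.
#'
#' @param m pi-bond oxygen fraction in \[0, 1\].
#' @param n pi-bond sulfur fraction in \[0, 1\].
#' @param aromaticThreshold aromaticity-equivalent threshold.
#' @return list with class `DescriptorConfig`.
#' @export
descriptorConfig <- function(m = 0.5, n = 0.5, aromaticThreshold = 2.5) {
  stopifnot(is.numeric(m), length(m) == 1, m >= 0, m <= 1,
            is.numeric(n), length(n) == 1, n >= 0, n <= 1,
            is.numeric(aromaticThreshold), length(aromaticThreshold) == 1)
  structure(list(m = m, n = n, aromaticThreshold = aromaticThreshold),
            class = "DescriptorConfig")
}

#' Compound-class assignment
#'
#' Assigns the heteroatom class used throughout the analysis: `CHO` (only C,
#' H and O, each present), `CHNO`, `CHNOS`, `CHOS` (exact element sets), and
#' `other` for everything else (e.g. Cl- or P-bearing formulas, CHN, CHNS,
#' or formulas missing oxygen).
#'
#' @param formulas character vector of formulas (or a single parsed count
#'   vector from [parseFormula()]).
#' @return character vector of class labels.
#' @export
compoundClass <- function(formulas) {
  one <- function(ct) {
    present <- sort(names(ct[ct > 0]))
    if (identical(present, sort(c("C", "H", "O")))) return("CHO")
    if (identical(present, sort(c("C", "H", "N", "O")))) return("CHNO")
    if (identical(present, sort(c("C", "H", "N", "O", "S")))) return("CHNOS")
    if (identical(present, sort(c("C", "H", "O", "S")))) return("CHOS")
    "other"
  }
  if (is.numeric(formulas) && !is.null(names(formulas))) return(one(formulas))
  vapply(formulas, function(f) one(parseFormula(f)), character(1),
         USE.NAMES = FALSE)
}

#' Double-bond equivalent
#'
#' DBE = C - H/2 + N/2 + 1, where H counts hydrogen plus halogen atoms
#' (F, Cl, Br, I). No clamping is applied; exotic inputs may yield negative
#' values. The result is an integer whenever H (including halogens) and N
#' have the same parity, otherwise a half-integer.
#'
#' @param formulas character vector of formulas or a parsed count vector.
#' @return numeric vector of DBE values.
#' @examples
#' dbe("C4H6O4")   # 2
#' dbe("C6H5NO3")  # 5
#' @export
dbe <- function(formulas) {
  one <- function(ct) {
    hal <- sum(vapply(HALOGENS, function(s) .count(ct, s), numeric(1)))
    .count(ct, "C") - (.count(ct, "H") + hal) / 2 + .count(ct, "N") / 2 + 1
  }
  if (is.numeric(formulas) && !is.null(names(formulas))) return(one(formulas))
  vapply(formulas, function(f) one(parseFormula(f)), numeric(1),
         USE.NAMES = FALSE)
}

#' Aromaticity equivalent
#'
#' A DBE-based aromaticity index correcting for pi-bonded heteroatoms:
#' with d = DBE - (m O + n S), the index is (3 d - 2) / d, clamped to 0 when
#' negative; a non-positive d (pi-corrected DBE exhausted by heteroatoms) also
#' yields 0. Values at or above the threshold (default 2.5) flag likely
#' aromatic molecules; the index is conservative and can under-count
#' aromatics (e.g. C8H8O3 scores 2.4 yet is compatible with vanillin).
#'
#' @param formulas character vector of formulas or a parsed count vector.
#' @param config a [descriptorConfig()].
#' @return numeric vector of aromaticity-equivalent values, always >= 0.
#' @examples
#' aromaticityEquivalent("C8H8O3")  # 2.4286
#' @export
aromaticityEquivalent <- function(formulas, config = descriptorConfig()) {
  one <- function(ct) {
    d <- dbe(ct) - (config$m * .count(ct, "O") + config$n * .count(ct, "S"))
    if (d <= 0) return(0)
    max(0, (3 * d - 2) / d)
  }
  if (is.numeric(formulas) && !is.null(names(formulas))) return(one(formulas))
  vapply(formulas, function(f) one(parseFormula(f)), numeric(1),
         USE.NAMES = FALSE)
}

#' Average carbon oxidation state
#'
#' OSc = 2 O/C - H/C. Tracks oxidative aging: highly oxidised molecules have
#' higher values; alkanes approach -2 from below as chain length grows.
#'
#' @param formulas character vector of formulas or a parsed count vector.
#' @return numeric vector.
#' @export
carbonOxidationState <- function(formulas) {
  one <- function(ct) {
    C <- .count(ct, "C")
    if (C <= 0) stop("carbon oxidation state undefined for zero-carbon formula")
    2 * .count(ct, "O") / C - .count(ct, "H") / C
  }
  if (is.numeric(formulas) && !is.null(names(formulas))) return(one(formulas))
  vapply(formulas, function(f) one(parseFormula(f)), numeric(1),
         USE.NAMES = FALSE)
}

# Kroll-diagram OSc bands. Closed intervals; they overlap by construction, so
# a molecule can carry several labels.
KROLL_BANDS <- list(
  `monoterpene-oxidation` = c(-1.0, -0.5),
  `isoprene-OH`           = c(-0.8, -0.2),
  SVOC                    = c(-0.5,  0.0),
  LVOC                    = c( 0.0,  0.9),
  `hydrocarbon-like`      = c(-1.7, -1.6)
)

#' Van Krevelen and Kroll region annotation
#'
#' The Van Krevelen region splits molecules at H/C = 1.5 into `aliphatic`
#' (H/C >= 1.5) versus `unsaturated/aromatic-leaning`. Kroll regions are the
#' set of volatility/precursor bands whose closed OSc interval contains the
#' molecule's carbon oxidation state: monoterpene oxidation products
#' (-1 <= OSc <= -0.5), isoprene + OH products (-0.8 <= OSc <= -0.2),
#' semi-volatile oxygenated compounds (-0.5 <= OSc <= 0), low-volatility
#' oxygenated compounds (0 <= OSc <= 0.9) and hydrocarbon-like molecules
#' (-1.7 <= OSc <= -1.6). Bands overlap, so the annotation is a set.
#'
#' @param osc numeric vector of carbon oxidation states.
#' @param hc numeric vector of H/C ratios (recycled against `osc`).
#' @return list with `vk_region` (character) and `kroll_regions`
#'   (list of character vectors, possibly empty).
#' @export
annotateRegions <- function(osc, hc) {
  stopifnot(is.numeric(osc), is.numeric(hc))
  hc <- rep_len(hc, length(osc))
  vk <- ifelse(hc >= 1.5, "aliphatic", "unsaturated/aromatic-leaning")
  kroll <- lapply(osc, function(x) {
    names(KROLL_BANDS)[vapply(KROLL_BANDS, function(b) {
      x >= b[1] && x <= b[2]
    }, logical(1))]
  })
  list(vk_region = vk, kroll_regions = kroll)
}

#' Per-molecule descriptor table
#'
#' Computes every per-molecule quantity used downstream: carbon number,
#' O/C, H/C, DBE, aromaticity equivalent, carbon oxidation state, compound
#' class, aromatic flag and region annotations. Descriptors are stored at
#' full precision; round only for display.
#'
#' @param formulas character vector of Hill-notation formulas (names, if
#'   present, become the `id` column).
#' @param config a [descriptorConfig()].
#' @return `data.frame` with columns id, formula, nC, oc_ratio, hc_ratio,
#'   dbe, chi_c, osc, compound_class, is_aromatic, vk_region and a list
#'   column kroll_regions.
#' @export
computeDescriptors <- function(formulas, config = descriptorConfig()) {
  stopifnot(is.character(formulas), length(formulas) > 0)
  ids <- if (!is.null(names(formulas))) names(formulas) else
    sprintf("M%04d", seq_along(formulas))
  ec <- elementCounts(formulas)
  if (any(ec[, "C"] <= 0)) {
    stop("all formulas must contain carbon")
  }
  d <- dbe(formulas)
  chi <- aromaticityEquivalent(formulas, config)
  oc <- ec[, "O"] / ec[, "C"]
  hc <- ec[, "H"] / ec[, "C"]
  osc <- 2 * oc - hc
  reg <- annotateRegions(osc, hc)
  data.frame(
    id = ids,
    formula = unname(formulas),
    nC = unname(ec[, "C"]),
    oc_ratio = unname(oc),
    hc_ratio = unname(hc),
    dbe = d,
    chi_c = chi,
    osc = unname(osc),
    compound_class = compoundClass(formulas),
    is_aromatic = chi >= config$aromaticThreshold,
    vk_region = reg$vk_region,
    kroll_regions = I(reg$kroll_regions),
    stringsAsFactors = FALSE
  )
}

#' Fraction of aromatic molecules
#'
#' Share of molecules whose aromaticity equivalent reaches the aromatic
#' threshold, as a percentage.
#'
#' @param descriptors a descriptor table from [computeDescriptors()].
#' @return percentage in \[0, 100\].
#' @export
aromaticFraction <- function(descriptors) {
  100 * mean(descriptors$is_aromatic)
}

#' Export a descriptor table as delimited text
#'
#' Writes one row per molecule; the set-valued Kroll annotation is serialised
#' as a `;`-separated field.
#'
#' @param descriptors table from [computeDescriptors()].
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeDescriptors <- function(descriptors, path) {
  out <- descriptors
  out$kroll_regions <- vapply(descriptors$kroll_regions, paste,
                              character(1), collapse = ";")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
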