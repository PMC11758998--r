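# Delimited-text I/O for feature tables and sample metadata. Comma and tab
# separators are auto-detected from the header line.

.detectSep <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (lengths(regmatches(hdr, gregexpr("\t", hdr))) > 0) "\t" else ","
}

.readDelim <- function(path) {
  utils::read.table(path, header = TRUE, sep = .detectSep(path),
                    stringsAsFactors = FALSE, check.names = FALSE,
                    quote = "\"", comment.char = "")
}

#' Read sample metadata
#'
#' Reads a delimited table with columns `sample_id`, `depth_m`, `year_ce`
#' and `enrichment_factor` (pre-concentration ratio of the melted ice).
#'
#' @param path delimited text file (comma or tab separated).
#' @return `data.frame` ordered as in the file.
#' @export
readSampleMeta <- function(path) {
  df <- .readDelim(path)
  need <- c("sample_id", "depth_m", "year_ce", "enrichment_factor")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("sample metadata missing column(s): ", paste(miss, collapse = ", "))
  if (any(df$enrichment_factor <= 0)) stop("enrichment_factor must be > 0")
  df$sample_id <- as.character(df$sample_id)
  df
}

#' Read a feature table into an NTSExperiment
#'
#' The file holds one row per molecular profile with fixed columns `id`,
#' `mz`, `rt`, `formula`, `peak_rating`, `group_cv`, `is_background`,
#' optional blank-intensity columns `blank_1`, `blank_2`, ... and one
#' intensity column per sample id in `samples`. Blank formula cells become
#' `NA`; missing intensity cells are read as 0 (below detection).
#'
#' @param path delimited text file.
#' @param samples sample metadata `data.frame` from [readSampleMeta()].
#' @return an [NTSExperiment].
#' @export
readFeatureTable <- function(path, samples) {
  df <- .readDelim(path)
  fixed <- c("id", "mz", "rt", "formula", "peak_rating", "group_cv",
             "is_background")
  miss <- setdiff(fixed, names(df))
  if (length(miss))
    stop("feature table missing column(s): ", paste(miss, collapse = ", "))
  blankCols <- grep("^blank_[0-9]+$", names(df), value = TRUE)
  sampleCols <- setdiff(names(df), c(fixed, blankCols))
  unknown <- setdiff(sampleCols, samples$sample_id)
  if (length(unknown))
    stop("intensity column(s) without sample metadata: ",
         paste(unknown, collapse = ", "))
  sampleCols <- samples$sample_id[samples$sample_id %in% sampleCols]
  if (!length(sampleCols)) stop("no intensity columns match the sample metadata")

  intens <- as.matrix(df[, sampleCols, drop = FALSE])
  storage.mode(intens) <- "double"
  intens[is.na(intens)] <- 0
  rownames(intens) <- df$id

  blanks <- if (length(blankCols)) {
    b <- as.matrix(df[, blankCols, drop = FALSE]); storage.mode(b) <- "double"
    b[is.na(b)] <- 0; b
  } else matrix(0, nrow(df), 1)
  form <- as.character(df$formula)
  form[!nzchar(trimws(ifelse(is.na(form), "", form)))] <- NA_character_
  form[is.na(df$formula)] <- NA_character_

  rd <- data.frame(
    mz = df$mz, rt = df$rt, formula = form,
    peak_rating = df$peak_rating, group_cv = df$group_cv,
    is_background = as.logical(df$is_background),
    blank_max = apply(blanks, 1, max),
    row.names = df$id, stringsAsFactors = FALSE)
  cd <- samples[match(sampleCols, samples$sample_id), , drop = FALSE]
  rownames(cd) <- cd$sample_id
  message(sprintf("read %d profiles x %d samples from %s",
                  nrow(df), length(sampleCols), path))
  NTSExperiment(intens, rd, cd)
}

#' Write an NTSExperiment back to delimited text
#'
#' Inverse of [readFeatureTable()]: fixed columns, a single `blank_1` column
#' carrying the per-profile blank maximum, then one intensity column per
#' sample.
#'
#' @param x an [NTSExperiment].
#' @param path output path (`.csv` comma-separated).
#' @return invisibly, the path.
#' @export
writeFeatureTable <- function(x, path) {
  rd <- as.data.frame(rowData(x))
  out <- data.frame(
    id = rownames(x), mz = rd$mz, rt = rd$rt,
    formula = ifelse(is.na(rd$formula), "", rd$formula),
    peak_rating = rd$peak_rating, group_cv = rd$group_cv,
    is_background = rd$is_background,
    blank_1 = if ("blank_max" %in% names(rd)) rd$blank_max else 0,
    stringsAsFactors = FALSE, check.names = FALSE)
  out <- cbind(out, as.data.frame(intensityMatrix(x), check.names = FALSE))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write sample metadata
#' @param samples sample metadata `data.frame`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeSampleMeta <- function(samples, path) {
  utils::write.csv(samples, path, row.names = FALSE)
  invisible(path)
}

#' Read a proxy series
#'
#' Delimited text with columns `year` and `value` (e.g. nitrate or sulfate
#' concentration, ozone mixing ratio, OH concentration). Years must be
#' strictly increasing.
#'
#' @param path delimited text file.
#' @param name optional label; defaults to the file name sans extension.
#' @return `data.frame` with attributes `name`.
#' @export
readProxy <- function(path, name = NULL) {
  df <- .readDelim(path)
  if (!all(c("year", "value") %in% names(df)))
    stop("proxy file must have columns 'year' and 'value'")
  if (is.unsorted(df$year, strictly = TRUE))
    stop("proxy years must be strictly increasing")
  attr(df, "name") <- if (is.null(name))
    sub("\\.[^.]*$", "", basename(path)) else name
  df
}
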