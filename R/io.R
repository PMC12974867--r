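## Readers and writers for the plain-text interchange formats. All CSV files
## are comma-separated, UTF-8, "." decimal, header required. Interpolated
## (fractional) years are serialized with one decimal place.

.read_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty file: ", path, call. = FALSE)
  df
}

.require_numeric <- function(df, cols, path) {
  for (col in cols) {
    if (is.null(df[[col]]))
      stop(sprintf("%s: missing column '%s'", path, col), call. = FALSE)
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad))
      stop(sprintf("%s: non-numeric cell '%s' in column '%s', row %d",
                   path, df[[col]][bad[1]], col, bad[1]), call. = FALSE)
    df[[col]] <- v
  }
  df
}

#' Read and write a per-core isotope series
#'
#' The CSV must carry header columns `sample_number` and `delta13C`. Rows are
#' sorted by sample number on read; all [isotope_series()] invariants are
#' enforced with a diagnostic naming the offending row.
#'
#' @param path CSV file path.
#' @param tree_id core label; defaults to the file name without extension.
#' @param d13c_range plausibility window passed to [isotope_series()].
#' @return an [isotope_series()].
#' @export
read_isotope_series <- function(path, tree_id = NULL, d13c_range = c(-40, 0)) {
  df <- .require_numeric(.read_csv(path), c("sample_number", "delta13C"), path)
  if (is.null(tree_id)) tree_id <- sub("\\.[^.]*$", "", basename(path))
  isotope_series(tree_id, df$sample_number, df$delta13C,
                 d13c_range = d13c_range)
}

#' @rdname read_isotope_series
#' @param x an [isotope_series()] to serialize.
#' @export
write_isotope_series <- function(x, path) {
  stopifnot(inherits(x, "isotope_series"))
  utils::write.csv(x$samples, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a radiocarbon calibration curve file
#'
#' Accepts IntCal-style columnar text: calendar age (cal BP), curve value
#' (14C age BP or F14C) and one-sigma curve error in the first three columns;
#' additional columns are ignored. Both comma- and whitespace-separated
#' layouts are accepted, and lines starting with `#` are comments.
#'
#' @param path curve file path.
#' @param era `"pre_bomb"` or `"post_bomb_F14C"`; curve files do not state
#'   their era, so the caller selects it.
#' @return a [calibration_curve()].
#' @export
read_calibration_curve <- function(path, era = c("pre_bomb", "post_bomb_F14C")) {
  era <- match.arg(era)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("empty curve file: ", path, call. = FALSE)
  sep <- if (grepl(",", lines[1], fixed = TRUE)) "," else ""
  df <- utils::read.table(text = lines, sep = sep, header = FALSE,
                          stringsAsFactors = FALSE)
  ## a non-numeric first row is a header line
  if (!is.numeric(df[[1]])) {
    df <- utils::read.table(text = lines, sep = sep, header = TRUE,
                            stringsAsFactors = FALSE)
  }
  if (ncol(df) < 3L)
    stop(path, ": curve needs >= 3 columns (cal BP, value, sigma)",
         call. = FALSE)
  calibration_curve(as.numeric(df[[1]]), as.numeric(df[[2]]),
                    as.numeric(df[[3]]), era = era)
}

#' Read and write annual records (atmospheric, CO2, rainfall, forcing)
#'
#' CSV with header columns `year` and `value`.
#'
#' @param path CSV file path.
#' @param kind record kind, see [annual_record()].
#' @param max_gap largest tolerated year gap, see [annual_record()].
#' @return an [annual_record()].
#' @export
read_annual_record <- function(path, kind, max_gap = Inf) {
  df <- .require_numeric(.read_csv(path), c("year", "value"), path)
  annual_record(df$year, df$value, kind = kind, max_gap = max_gap)
}

#' @rdname read_annual_record
#' @param x an [annual_record()] to serialize.
#' @export
write_annual_record <- function(x, path) {
  stopifnot(inherits(x, "annual_record"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a radiocarbon dates table
#'
#' CSV with header columns `tree_id`, `sample_number`, `measurement_type`,
#' `value`, `sigma` and optional `flagged_outlier`.
#'
#' @param path CSV file path.
#' @param series optional isotope series for referential validation, see
#'   [radiocarbon_dates()].
#' @return a validated `radiocarbon_dates` data frame.
#' @export
read_radiocarbon_dates <- function(path, series = NULL) {
  df <- .read_csv(path)
  df <- .require_numeric(df, c("sample_number", "value", "sigma"), path)
  radiocarbon_dates(df, series = series)
}

#' Read a tie-point table
#'
#' CSV with header columns `tree_id`, `sample_number`, `year_CE`.
#'
#' @param path CSV file path.
#' @return a validated `tie_points` data frame.
#' @export
read_tie_points <- function(path) {
  df <- .require_numeric(.read_csv(path), c("sample_number", "year_CE"), path)
  tie_points(df)
}

#' Read and write a dated series (year, delta13C)
#'
#' Dated series are the hand-off format between the age model and the isotope
#' corrections: one row per sample with its interpolated calendar year (CE,
#' possibly fractional, written with one decimal) and delta 13C value.
#'
#' @param path CSV file path.
#' @return data frame with columns `year`, `delta13C`, sorted by year.
#' @export
read_dated_series <- function(path) {
  df <- .require_numeric(.read_csv(path), c("year", "delta13C"), path)
  df <- df[order(df$year), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' @rdname read_dated_series
#' @param x data frame with columns `year`, `delta13C`.
#' @export
write_dated_series <- function(x, path) {
  out <- data.frame(year = sprintf("%.1f", x$year), delta13C = x$delta13C)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.log_msg <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}
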