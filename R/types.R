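#' @keywords internal
"_PACKAGE"

## Year convention: all user-facing years are calendar years CE.  Radiocarbon
## internals work in cal BP with BP = 1950 - CE.  The conversion lives here and
## nowhere else, so it round-trips exactly.

#' Convert calendar years CE to cal BP (and back)
#'
#' Cal BP is defined as years before 1950 CE. These two helpers are the single
#' place in the package where the convention is applied.
#'
#' @param year_CE,cal_BP numeric vectors of years.
#' @return numeric vector of converted years.
#' @examples
#' ce_to_bp(1950)  # 0
#' bp_to_ce(500)   # 1450
#' @export
ce_to_bp <- function(year_CE) 1950 - year_CE

#' @rdname ce_to_bp
#' @export
bp_to_ce <- function(cal_BP) 1950 - cal_BP

.stop_row <- function(row, msg, ...) {
  stop(sprintf("row %s: %s", paste(row, collapse = ", "), sprintf(msg, ...)),
       call. = FALSE)
}

#' Construct a validated per-core isotope series
#'
#' An isotope series holds ordered delta 13C measurements along one tree core,
#' indexed by sample number counted from the bark (sample 1 = outermost,
#' youngest) inward. Values are per mille relative to VPDB.
#'
#' @param tree_id short core label, e.g. `"DFL"`.
#' @param sample_number positive integer sample indices, bark side = 1.
#' @param delta13C per-mille VPDB values, one per sample.
#' @param metadata optional named list (species, coordinates, core length...).
#' @param d13c_range plausibility window in per mille; values outside it are
#'   rejected. The default covers the full C3 plant range.
#' @return an object of class `isotope_series` with elements `tree_id`,
#'   `samples` (data frame with columns `sample_number`, `delta13C`, sorted by
#'   sample number) and `metadata`.
#' @export
isotope_series <- function(tree_id, sample_number, delta13C,
                           metadata = list(), d13c_range = c(-40, 0)) {
  if (length(tree_id) != 1L || !nzchar(tree_id))
    stop("tree_id must be a single non-empty label", call. = FALSE)
  if (length(sample_number) != length(delta13C))
    stop("sample_number and delta13C lengths differ", call. = FALSE)
  if (length(sample_number) == 0L)
    stop("empty isotope series", call. = FALSE)
  sample_number <- as.numeric(sample_number)
  delta13C <- as.numeric(delta13C)
  bad <- which(!is.finite(sample_number) | sample_number <= 0 |
                 sample_number != round(sample_number))
  if (length(bad))
    .stop_row(bad[1], "sample_number must be a positive integer (got %s)",
              sample_number[bad[1]])
  dup <- sample_number[duplicated(sample_number)]
  if (length(dup))
    .stop_row(which(sample_number == dup[1]),
              "duplicate sample_number %d", as.integer(dup[1]))
  bad <- which(!is.finite(delta13C) | delta13C < d13c_range[1] |
                 delta13C > d13c_range[2])
  if (length(bad))
    .stop_row(bad[1],
              "delta13C %.3f outside plausibility window [%g, %g]",
              delta13C[bad[1]], d13c_range[1], d13c_range[2])
  ord <- order(sample_number)
  structure(
    list(tree_id = tree_id,
         samples = data.frame(sample_number = as.integer(sample_number[ord]),
                              delta13C = delta13C[ord]),
         metadata = metadata),
    class = "isotope_series")
}

#' @export
print.isotope_series <- function(x, ...) {
  cat(sprintf("<isotope_series> %s: %d samples (sample %d..%d), d13C %.2f..%.2f permil\n",
              x$tree_id, nrow(x$samples),
              min(x$samples$sample_number), max(x$samples$sample_number),
              min(x$samples$delta13C), max(x$samples$delta13C)))
  invisible(x)
}

#' Construct a validated annual record
#'
#' Annual records carry atmospheric delta 13C, CO2 concentration, rainfall, or
#' a climate forcing index on a strictly increasing integer year grid (CE).
#'
#' @param year integer years CE, strictly increasing.
#' @param value numeric values.
#' @param kind one of `"d13c_atm"` (per mille), `"co2"` (ppm), `"rainfall"`
#'   (mm/yr), `"forcing_index"` (unitless), `"instrumental_rain"` (mm/yr).
#' @param max_gap largest tolerated gap in years between consecutive entries;
#'   records feeding the isotope corrections should be gap-free (`1`).
#' @return a data frame with columns `year`, `value` and class
#'   `annual_record`; the kind is kept in the `"kind"` attribute.
#' @export
annual_record <- function(year, value,
                          kind = c("d13c_atm", "co2", "rainfall",
                                   "forcing_index", "instrumental_rain"),
                          max_gap = Inf) {
  kind <- match.arg(kind)
  if (length(year) != length(value) || length(year) == 0L)
    stop("year and value must be equal-length, non-empty", call. = FALSE)
  year <- as.numeric(year)
  if (any(!is.finite(year)) || any(year != round(year)))
    stop("years must be finite integers (CE)", call. = FALSE)
  if (any(diff(year) <= 0)) {
    i <- which(diff(year) <= 0)[1]
    .stop_row(i + 1L, "years not strictly increasing at %d", year[i + 1L])
  }
  if (any(diff(year) > max_gap)) {
    i <- which(diff(year) > max_gap)[1]
    .stop_row(i + 1L, "gap of %d years exceeds max_gap = %g",
              as.integer(diff(year)[i]), max_gap)
  }
  if (any(!is.finite(value)))
    .stop_row(which(!is.finite(value))[1], "non-finite value")
  structure(data.frame(year = as.integer(year), value = as.numeric(value)),
            kind = kind, class = c("annual_record", "data.frame"))
}

#' Construct a validated radiocarbon calibration curve
#'
#' A calibration curve maps calendar age (cal BP) to a radiocarbon measurement
#' scale: conventional 14C age BP for the pre-bomb era, or F14C (fraction
#' modern) for the post-bomb era, with a one-standard-deviation curve
#' uncertainty at each knot. Queries between knots are linearly interpolated;
#' queries outside the grid are errors.
#'
#' @param cal_BP calendar ages of the knots, strictly monotone.
#' @param mu curve value at each knot (14C age BP, or F14C for bomb curves).
#' @param sigma curve one-sigma uncertainty, same units as `mu`, all `>= 0`.
#' @param era `"pre_bomb"` (conventional 14C ages) or `"post_bomb_F14C"`.
#' @return an object of class `calibration_curve`: a list with the knot grid
#'   (sorted by increasing `cal_BP`) and the era tag.
#' @export
calibration_curve <- function(cal_BP, mu, sigma,
                              era = c("pre_bomb", "post_bomb_F14C")) {
  era <- match.arg(era)
  n <- length(cal_BP)
  if (n < 2L || length(mu) != n || length(sigma) != n)
    stop("curve needs >= 2 knots with matching mu and sigma", call. = FALSE)
  if (any(!is.finite(cal_BP)) || any(!is.finite(mu)) || any(!is.finite(sigma)))
    stop("curve contains non-finite values", call. = FALSE)
  d <- diff(cal_BP)
  if (!(all(d > 0) || all(d < 0))) {
    i <- which(sign(d) != sign(d[1]) | d == 0)[1]
    .stop_row(i + 1L, "cal BP axis not strictly monotone at %g", cal_BP[i + 1L])
  }
  if (any(sigma < 0))
    .stop_row(which(sigma < 0)[1], "negative curve sigma")
  ord <- order(cal_BP)
  structure(list(grid = data.frame(cal_BP = cal_BP[ord], mu = mu[ord],
                                   sigma = sigma[ord]),
                 era = era),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> era %s, %d knots, cal BP %g..%g\n",
              x$era, nrow(x$grid), min(x$grid$cal_BP), max(x$grid$cal_BP)))
  invisible(x)
}

#' Interpolate a calibration curve at given calendar ages
#'
#' @param curve a [calibration_curve()].
#' @param cal_BP calendar ages to query; must lie inside the knot grid.
#' @return a data frame with columns `mu` and `sigma` at the queried ages.
#' @export
curve_at <- function(curve, cal_BP) {
  g <- curve$grid
  rng <- range(g$cal_BP)
  if (any(cal_BP < rng[1] | cal_BP > rng[2]))
    stop(sprintf("query at cal BP %g outside curve support [%g, %g]",
                 cal_BP[which(cal_BP < rng[1] | cal_BP > rng[2])[1]],
                 rng[1], rng[2]), call. = FALSE)
  data.frame(
    mu = stats::approx(g$cal_BP, g$mu, xout = cal_BP)$y,
    sigma = stats::approx(g$cal_BP, g$sigma, xout = cal_BP)$y)
}

#' Validate a table of radiocarbon dates
#'
#' @param df data frame with columns `tree_id`, `sample_number`,
#'   `measurement_type` (`"conventional_BP"` or `"F14C"`), `value`, `sigma`,
#'   and optional logical `flagged_outlier` (defaults to `FALSE`).
#' @param series optional [isotope_series()] (or list of them); when supplied,
#'   every date must reference an existing sample number of its series.
#' @return the validated data frame with class `radiocarbon_dates`.
#' @export
radiocarbon_dates <- function(df, series = NULL) {
  need <- c("tree_id", "sample_number", "measurement_type", "value", "sigma")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (is.null(df$flagged_outlier)) df$flagged_outlier <- FALSE
  df$flagged_outlier <- as.logical(df$flagged_outlier)
  ok_type <- df$measurement_type %in% c("conventional_BP", "F14C")
  if (any(!ok_type))
    .stop_row(which(!ok_type)[1], "unknown measurement_type '%s'",
              df$measurement_type[which(!ok_type)[1]])
  if (any(!is.finite(df$sigma) | df$sigma <= 0))
    .stop_row(which(!is.finite(df$sigma) | df$sigma <= 0)[1],
              "sigma must be > 0")
  f14 <- df$measurement_type == "F14C"
  if (any(f14 & (!is.finite(df$value) | df$value <= 0)))
    .stop_row(which(f14 & df$value <= 0)[1], "F14C value must be > 0")
  if (!is.null(series)) {
    if (inherits(series, "isotope_series")) series <- list(series)
    names(series) <- vapply(series, `[[`, "", "tree_id")
    for (i in seq_len(nrow(df))) {
      s <- series[[df$tree_id[i]]]
      if (is.null(s))
        .stop_row(i, "no isotope series for tree '%s'", df$tree_id[i])
      if (!df$sample_number[i] %in% s$samples$sample_number)
        .stop_row(i, "sample_number %d not present in series %s",
                  as.integer(df$sample_number[i]), df$tree_id[i])
    }
  }
  class(df) <- c("radiocarbon_dates", "data.frame")
  df
}

#' Validate a table of chronological tie points
#'
#' Tie points anchor (sample number, calendar year) pairs per tree. Within a
#' tree, year must be non-increasing as sample number increases (deeper rings
#' are older). A duplicated sample number is permitted only as a hiatus pair:
#' two years at one sample number, the larger (younger) year listed first.
#'
#' @param df data frame with columns `tree_id`, `sample_number`, `year_CE`.
#' @return the validated data frame with class `tie_points`, ordered by tree
#'   and sample number (hiatus pairs keep the younger year first).
#' @export
tie_points <- function(df) {
  need <- c("tree_id", "sample_number", "year_CE")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  out <- do.call(rbind, lapply(split(df, df$tree_id), function(d) {
    d <- d[order(d$sample_number, -d$year_CE), , drop = FALSE]
    dup <- unique(d$sample_number[duplicated(d$sample_number)])
    if (length(dup) > 1L)
      stop(sprintf("tree %s: more than one duplicated sample number",
                   d$tree_id[1]), call. = FALSE)
    if (length(dup) == 1L && sum(d$sample_number == dup) != 2L)
      stop(sprintf("tree %s: sample %d repeated more than twice",
                   d$tree_id[1], as.integer(dup)), call. = FALSE)
    if (any(diff(d$year_CE) > 0)) {
      i <- which(diff(d$year_CE) > 0)[1]
      stop(sprintf(
        "tree %s: year increases with depth at sample %d (inversion without hiatus flag)",
        d$tree_id[1], as.integer(d$sample_number[i + 1L])), call. = FALSE)
    }
    d
  }))
  rownames(out) <- NULL
  class(out) <- c("tie_points", "data.frame")
  out
}
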