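## Tie-point-constrained age models. Tie points are inputs, not estimates:
## cross-tree reconciliation of shared isotope signals ("wiggle matching") is
## expert work, and this module supplies the linear interpolation and the
## validation metrics that support it. Between tie points the growth rate is
## constant; a duplicated sample number with two years encodes a growth
## hiatus, an instantaneous jump in ring space.

#' Fit a piecewise-linear age model through tie points
#'
#' @param tp a [tie_points()] table (or coercible data frame) for one tree;
#'   at least two tie points. A duplicated sample number with two years (the
#'   larger year listed first) declares a growth hiatus at that ring.
#' @return an object of class `age_model` with `tree_id`, `knots` (data frame
#'   `sample_number`, `year_CE`), optional `hiatus` (list with
#'   `sample_number`, `year_stop_CE`, `year_resume_CE`) and `domain` (sample
#'   number range).
#' @details The model year strictly decreases as sample number increases.
#'   Growth stopped at `year_stop_CE` and resumed at `year_resume_CE`
#'   (`year_resume_CE > year_stop_CE`); queries at the hiatus ring itself
#'   return the older (stop-side) year.
#' @export
fit_age_model <- function(tp) {
  if (!inherits(tp, "tie_points")) tp <- tie_points(tp)
  if (length(unique(tp$tree_id)) != 1L)
    stop("fit_age_model() takes tie points for a single tree", call. = FALSE)
  if (nrow(tp) < 2L)
    stop("need at least 2 tie points", call. = FALSE)
  tp <- tp[order(tp$sample_number, -tp$year_CE), , drop = FALSE]
  dup <- unique(tp$sample_number[duplicated(tp$sample_number)])
  hiatus <- NULL
  if (length(dup) == 1L) {
    yrs <- tp$year_CE[tp$sample_number == dup]
    hiatus <- list(sample_number = dup,
                   year_stop_CE = min(yrs),    # growth stopped (older side)
                   year_resume_CE = max(yrs))  # growth resumed (younger side)
    if (hiatus$year_resume_CE <= hiatus$year_stop_CE)
      stop("hiatus pair must carry two distinct years", call. = FALSE)
  }
  ## strict decrease between distinct knots (the hiatus jump included)
  d_by_sample <- tp[!duplicated(paste(tp$sample_number, tp$year_CE)), ]
  seg_ok <- diff(d_by_sample$year_CE) < 0
  if (any(!seg_ok))
    stop("model year must strictly decrease with increasing sample number",
         call. = FALSE)
  structure(list(tree_id = tp$tree_id[1],
                 knots = data.frame(sample_number = tp$sample_number,
                                    year_CE = tp$year_CE),
                 hiatus = hiatus,
                 domain = range(tp$sample_number)),
            class = "age_model")
}

#' @export
print.age_model <- function(x, ...) {
  cat(sprintf("<age_model> %s: samples %g..%g, years %g..%g CE%s\n",
              x$tree_id, x$domain[1], x$domain[2],
              min(x$knots$year_CE), max(x$knots$year_CE),
              if (is.null(x$hiatus)) "" else
                sprintf(", hiatus at sample %g (%g-%g CE)",
                        x$hiatus$sample_number, x$hiatus$year_stop_CE,
                        x$hiatus$year_resume_CE)))
  invisible(x)
}

#' Evaluate an age model at given sample numbers
#'
#' @param model an [fit_age_model()] result.
#' @param sample_number numeric sample positions (fractional allowed).
#' @param extrapolate if `FALSE` (default) queries outside the model domain
#'   are errors; if `TRUE` they are clamped to the terminal knot years.
#' @return calendar years CE (possibly fractional).
#' @export
age_at <- function(model, sample_number, extrapolate = FALSE) {
  k <- model$knots
  outside <- sample_number < model$domain[1] | sample_number > model$domain[2]
  if (any(outside) && !extrapolate)
    stop(sprintf("sample %g outside age-model domain [%g, %g]",
                 sample_number[which(outside)[1]],
                 model$domain[1], model$domain[2]), call. = FALSE)
  s <- pmin(pmax(sample_number, model$domain[1]), model$domain[2])
  if (is.null(model$hiatus)) {
    return(stats::approx(k$sample_number, k$year_CE, xout = s)$y)
  }
  hs <- model$hiatus$sample_number
  outer_k <- k[k$sample_number < hs | (k$sample_number == hs &
                 k$year_CE == model$hiatus$year_resume_CE), ]
  inner_k <- k[k$sample_number > hs | (k$sample_number == hs &
                 k$year_CE == model$hiatus$year_stop_CE), ]
  y <- numeric(length(s))
  outer_q <- s < hs
  if (any(outer_q))
    y[outer_q] <- stats::approx(outer_k$sample_number, outer_k$year_CE,
                                xout = s[outer_q])$y
  if (any(!outer_q))
    y[!outer_q] <- stats::approx(inner_k$sample_number, inner_k$year_CE,
                                 xout = s[!outer_q])$y
  y
}

#' Assign calendar years to every sample of an isotope series
#'
#' @param model an [fit_age_model()] result for the same tree.
#' @param series an [isotope_series()].
#' @param extrapolate passed to [age_at()].
#' @return a dated series: data frame with columns `year` (CE) and `delta13C`,
#'   sorted ascending by year for downstream use.
#' @export
assign_ages <- function(model, series, extrapolate = FALSE) {
  stopifnot(inherits(series, "isotope_series"))
  y <- age_at(model, series$samples$sample_number, extrapolate = extrapolate)
  out <- data.frame(year = y, delta13C = series$samples$delta13C)
  out <- out[order(out$year), , drop = FALSE]
  rownames(out) <- NULL
  .log_msg("agemodel", "%s: dated %d samples, %0.1f..%0.1f CE",
           series$tree_id, nrow(out), min(out$year), max(out$year))
  out
}

#' Validate an age model against calibrated radiocarbon dates
#'
#' Each date's model year is tested for membership of the union of its HPD
#' intervals (the 1-sigma calibration ranges at default coverage). Dates
#' flagged as outliers are reported but excluded from the summary counts.
#'
#' @param model an [fit_age_model()] result.
#' @param cal_dates list of `calibrated_date` objects for the same tree.
#' @return a `validation_report`: list with `dates` (per-date data frame:
#'   `tree_id`, `sample_number`, `model_year_CE`, `inside_1sigma`,
#'   `distance_to_nearest_interval`, `flagged_outlier`) and `summary`
#'   (`n_dates`, `n_checked`, `n_inside`, `fraction_inside`).
#' @export
validate_model <- function(model, cal_dates) {
  if (length(cal_dates) == 0L) stop("no calibrated dates supplied", call. = FALSE)
  rows <- lapply(cal_dates, function(cd) {
    y <- age_at(model, cd$sample_number)
    iv <- cd$hpd_intervals
    inside <- any(y >= iv$start_CE & y <= iv$end_CE)
    dist <- if (inside) 0 else min(pmax(iv$start_CE - y, 0, y - iv$end_CE))
    data.frame(tree_id = cd$tree_id, sample_number = cd$sample_number,
               model_year_CE = y, inside_1sigma = inside,
               distance_to_nearest_interval = dist,
               flagged_outlier = cd$flagged_outlier)
  })
  dates <- do.call(rbind, rows)
  chk <- dates[!dates$flagged_outlier, , drop = FALSE]
  summary <- list(n_dates = nrow(dates), n_checked = nrow(chk),
                  n_inside = sum(chk$inside_1sigma),
                  fraction_inside =
                    if (nrow(chk)) mean(chk$inside_1sigma) else NA_real_)
  .log_msg("agemodel", "%s: %d/%d unflagged dates inside 1-sigma",
           model$tree_id, summary$n_inside, summary$n_checked)
  structure(list(dates = dates, summary = summary),
            class = "validation_report")
}

#' Detect stratigraphic age inversions among calibrated dates
#'
#' Within a core, a smaller sample number (nearer the bark) must be younger.
#' A pair is flagged when the shallower date's entire 1-sigma range is older
#' than the deeper date's entire range: the ranges are disjoint and in the
#' wrong stratigraphic order, the signature of a mislabeled sample.
#'
#' @param cal_dates list of `calibrated_date` objects for one tree.
#' @return data frame of flagged pairs (`sample_number_young`,
#'   `sample_number_old`, `range_young_end_CE`, `range_old_start_CE`); zero
#'   rows when the sequence is clean.
#' @export
detect_inversions <- function(cal_dates) {
  if (length(cal_dates) < 2L)
    return(data.frame(sample_number_young = integer(), sample_number_old = integer(),
                      range_young_end_CE = numeric(), range_old_start_CE = numeric()))
  sn <- vapply(cal_dates, `[[`, numeric(1), "sample_number")
  cal_dates <- cal_dates[order(sn)]
  lo <- vapply(cal_dates, function(cd) min(cd$hpd_intervals$start_CE), 0)
  hi <- vapply(cal_dates, function(cd) max(cd$hpd_intervals$end_CE), 0)
  sn <- sort(sn)
  out <- list()
  for (i in seq_len(length(cal_dates) - 1L)) {
    for (j in (i + 1L):length(cal_dates)) {
      ## i is the younger ring (smaller sample number): its range must not be
      ## entirely older (lower CE) than the deeper date's range
      if (hi[i] < lo[j]) {
        out[[length(out) + 1L]] <- data.frame(
          sample_number_young = sn[i], sample_number_old = sn[j],
          range_young_end_CE = hi[i], range_old_start_CE = lo[j])
      }
    }
  }
  if (!length(out))
    return(data.frame(sample_number_young = integer(), sample_number_old = integer(),
                      range_young_end_CE = numeric(), range_old_start_CE = numeric()))
  do.call(rbind, out)
}
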