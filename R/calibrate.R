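## Radiocarbon calibration. A measurement (14C age BP, or F14C for the bomb
## era) is converted to a normalized probability mass over an annual calendar
## grid: the likelihood at calendar year theta is Gaussian in the measured
## value around the interpolated curve mean, with variance sigma_lab^2 +
## sigma_curve(theta)^2. Highest-posterior-density (HPD) intervals summarise
## the density; the default 0.683 coverage mirrors the 1-sigma ranges used to
## validate age models.

.calibrate_gaussian <- function(value, sigma, curve, grid_step = 1) {
  g <- curve$grid
  bp_lo <- min(g$cal_BP); bp_hi <- max(g$cal_BP)
  ## annual CE grid covering the curve support
  ce <- seq(ceiling(bp_to_ce(bp_hi)), floor(bp_to_ce(bp_lo)), by = grid_step)
  at <- curve_at(curve, ce_to_bp(ce))
  w <- stats::dnorm(value, mean = at$mu, sd = sqrt(sigma^2 + at$sigma^2))
  tot <- sum(w)
  if (!is.finite(tot) || tot <= 0)
    stop("zero total calibration weight: measurement outside curve support",
         call. = FALSE)
  data.frame(year_CE = ce, prob = w / tot)
}

.new_calibrated_date <- function(date, density, coverage) {
  structure(list(tree_id = date$tree_id,
                 sample_number = date$sample_number,
                 density = density,
                 hpd_intervals = hpd(density, coverage),
                 coverage = coverage,
                 flagged_outlier = isTRUE(date$flagged_outlier)),
            class = "calibrated_date")
}

#' Calibrate a pre-bomb radiocarbon date
#'
#' @param date one-row data frame (or list) with fields `tree_id`,
#'   `sample_number`, `measurement_type = "conventional_BP"`, `value` (14C age
#'   BP), `sigma` (lab one-sigma) and optional `flagged_outlier`.
#' @param curve a [calibration_curve()] with era `"pre_bomb"`.
#' @param grid_step calendar grid step in years (default 1, matching the
#'   annual resolution of the rest of the pipeline).
#' @param coverage HPD coverage (default 0.683, i.e. 1-sigma).
#' @return a `calibrated_date`: normalized `density` over the calendar grid
#'   (sums to 1), `hpd_intervals` (data frame `start_CE`, `end_CE`, `mass`),
#'   plus identification fields.
#' @export
calibrate <- function(date, curve, grid_step = 1, coverage = 0.683) {
  if (!identical(curve$era, "pre_bomb"))
    stop("calibrate() needs a pre_bomb curve; use calibrate_postbomb() for F14C",
         call. = FALSE)
  if (!identical(as.character(date$measurement_type), "conventional_BP"))
    stop("calibrate() expects a conventional_BP measurement", call. = FALSE)
  if (date$sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  dens <- .calibrate_gaussian(date$value, date$sigma, curve, grid_step)
  .new_calibrated_date(date, dens, coverage)
}

#' Calibrate a post-bomb (F14C) radiocarbon date
#'
#' The bomb-era curve is non-monotone, so densities are routinely multimodal
#' and the HPD summary may consist of several disjoint intervals.
#'
#' @param date one-row data frame (or list) with `measurement_type = "F14C"`
#'   and `value`/`sigma` on the F14C scale.
#' @param curve a [calibration_curve()] with era `"post_bomb_F14C"`.
#' @inheritParams calibrate
#' @return a `calibrated_date`, as for [calibrate()].
#' @export
calibrate_postbomb <- function(date, curve, grid_step = 1, coverage = 0.683) {
  if (!identical(curve$era, "post_bomb_F14C"))
    stop("calibrate_postbomb() needs a post_bomb_F14C curve", call. = FALSE)
  if (!identical(as.character(date$measurement_type), "F14C"))
    stop("calibrate_postbomb() expects an F14C measurement", call. = FALSE)
  if (date$sigma <= 0 || date$value <= 0)
    stop("F14C value and sigma must be > 0", call. = FALSE)
  dens <- .calibrate_gaussian(date$value, date$sigma, curve, grid_step)
  .new_calibrated_date(date, dens, coverage)
}

#' Calibrate a table of radiocarbon dates
#'
#' Dispatches each row to [calibrate()] or [calibrate_postbomb()] according to
#' its `measurement_type`.
#'
#' @param dates a [radiocarbon_dates()] table.
#' @param curve pre-bomb [calibration_curve()].
#' @param postbomb_curve post-bomb curve; required if any date is F14C.
#' @inheritParams calibrate
#' @return list of `calibrated_date` objects, in row order.
#' @export
calibrate_dates <- function(dates, curve, postbomb_curve = NULL,
                            grid_step = 1, coverage = 0.683) {
  lapply(seq_len(nrow(dates)), function(i) {
    d <- dates[i, ]
    if (d$measurement_type == "F14C") {
      if (is.null(postbomb_curve))
        stop("F14C date present but no postbomb_curve supplied", call. = FALSE)
      calibrate_postbomb(d, postbomb_curve, grid_step, coverage)
    } else {
      calibrate(d, curve, grid_step, coverage)
    }
  })
}

#' Highest-posterior-density intervals of a calendar-year density
#'
#' Grid years are accumulated in order of decreasing probability (ties broken
#' toward earlier years, for determinism) until the requested coverage is
#' reached; contiguous runs of selected years are merged into intervals. The
#' result is the smallest set of grid years whose total mass is at least
#' `coverage`.
#'
#' @param density data frame with columns `year_CE` and `prob` (normalized).
#' @param coverage required probability mass, in (0, 1).
#' @return data frame with columns `start_CE`, `end_CE`, `mass`, disjoint and
#'   sorted by `start_CE`.
#' @export
hpd <- function(density, coverage = 0.683) {
  if (!is.numeric(coverage) || coverage <= 0 || coverage >= 1)
    stop("coverage must be in (0, 1)", call. = FALSE)
  yr <- density$year_CE
  p <- density$prob
  ord <- order(-p, yr)
  k <- which(cumsum(p[ord]) >= coverage - 1e-12)[1]
  if (is.na(k)) k <- length(p)
  sel <- sort(yr[ord[seq_len(k)]])
  step <- if (length(yr) > 1) min(diff(sort(yr))) else 1
  brk <- c(0, which(diff(sel) > step + 1e-9), length(sel))
  out <- do.call(rbind, lapply(seq_len(length(brk) - 1L), function(i) {
    run <- sel[(brk[i] + 1L):brk[i + 1L]]
    data.frame(start_CE = run[1], end_CE = run[length(run)],
               mass = sum(p[yr >= run[1] & yr <= run[length(run)]]))
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.calibrated_date <- function(x, ...) {
  cat(sprintf("<calibrated_date> %s sample %s, %.1f%% HPD:\n",
              x$tree_id, x$sample_number, 100 * x$coverage))
  for (i in seq_len(nrow(x$hpd_intervals)))
    cat(sprintf("  %g..%g CE (%.1f%%)\n", x$hpd_intervals$start_CE[i],
                x$hpd_intervals$end_CE[i], 100 * x$hpd_intervals$mass[i]))
  invisible(x)
}

#' Flatten calibrated dates to an intervals table
#'
#' One row per HPD interval, the serialization used by the command-line
#' pipeline between the calibration and age-model stages.
#'
#' @param cal_dates list of `calibrated_date` objects.
#' @return data frame with columns `tree_id`, `sample_number`, `start_CE`,
#'   `end_CE`, `mass`, `flagged_outlier`.
#' @export
hpd_table <- function(cal_dates) {
  do.call(rbind, lapply(cal_dates, function(cd) {
    cbind(data.frame(tree_id = cd$tree_id, sample_number = cd$sample_number),
          cd$hpd_intervals,
          data.frame(flagged_outlier = cd$flagged_outlier))
  }))
}
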