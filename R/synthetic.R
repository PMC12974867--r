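## Ground-truth-known synthetic data. The generator emulates the statistical
## structure the analysis assumes for semi-arid baobab cores: a drying
## rainfall trend with centennial swings and AR(1) interannual noise, a
## negative linear rainfall -> delta 13C response, trees with constant radial
## growth (optionally interrupted by a hiatus), sparse radiocarbon dating
## against a wiggly calibration curve, and post-1850 atmospheric delta 13C
## decline with a CO2 rise. True values are kept alongside the observables so
## every pipeline stage can be tested by parameter recovery.

## derive a reproducible sub-seed (< 2^31) for a named component
.sub_seed <- function(seed, k) (as.integer(seed) %% 100000L) * 211L + k

#' Generate a synthetic annual rainfall series
#'
#' Linear trend + sinusoidal centennial component + AR(1) anomalies, clipped
#' at zero (clipping is logged).
#'
#' @param span `c(first_year, last_year)` CE, at least 100 years.
#' @param mean_mm long-term mean rainfall (default 450 mm/yr, the middle of a
#'   semi-arid 300-600 mm envelope).
#' @param trend_mm_per_century linear trend (default -15, a slow drying).
#' @param ar1_phi lag-1 autocorrelation of the anomalies, `|phi| < 1`.
#' @param centennial_amp_mm amplitude of the centennial sinusoid (default 60).
#' @param centennial_period_yr period of the sinusoid (default 200 years).
#' @param noise_sd_mm marginal standard deviation of the AR(1) anomalies.
#' @param seed integer seed; the series is bit-reproducible given the seed.
#' @return an [annual_record()] of kind `"rainfall"`.
#' @export
generate_rainfall <- function(span = c(1300, 2015), mean_mm = 450,
                              trend_mm_per_century = -15, ar1_phi = 0.6,
                              centennial_amp_mm = 60,
                              centennial_period_yr = 200,
                              noise_sd_mm = 40, seed = 1) {
  if (diff(span) < 100) stop("span must cover >= 100 years", call. = FALSE)
  if (abs(ar1_phi) >= 1) stop("|ar1_phi| must be < 1", call. = FALSE)
  years <- span[1]:span[2]
  t0 <- years - years[1]
  det <- mean_mm + trend_mm_per_century * (t0 - mean(t0)) / 100 +
    centennial_amp_mm * sin(2 * pi * t0 / centennial_period_yr)
  set.seed(.sub_seed(seed, 1L))
  innov_sd <- noise_sd_mm * sqrt(1 - ar1_phi^2)
  eps <- if (noise_sd_mm > 0)
    as.numeric(stats::arima.sim(list(ar = ar1_phi), n = length(years),
                                sd = innov_sd))
  else rep(0, length(years))
  r <- det + eps
  n_clip <- sum(r < 0)
  if (n_clip > 0) {
    r[r < 0] <- 0
    .log_msg("simulate", "rainfall: clipped %d negative years at 0", n_clip)
  }
  annual_record(years, r, kind = "rainfall")
}

#' Map rainfall to a true delta 13C signal
#'
#' The proxy model is the simplest form consistent with a monotone negative
#' rainfall response: `delta(t) = baseline + sensitivity * (rain(t) -
#' mean(rain)) / 100 + N(0, noise_sd)`.
#'
#' @param rain an [annual_record()] of kind `"rainfall"`.
#' @param baseline_permil long-term mean delta 13C (default -25.3 per mille).
#' @param sensitivity_permil_per_100mm response per 100 mm/yr of rainfall;
#'   must be negative (wetter = more negative).
#' @param noise_sd_permil additive signal noise (default 0.15, below the
#'   replication error of a well-run isotope lab).
#' @param seed integer seed.
#' @return data frame with columns `year` and `value`: the true ring signal.
#' @export
rainfall_to_d13c <- function(rain, baseline_permil = -25.3,
                             sensitivity_permil_per_100mm = -0.35,
                             noise_sd_permil = 0.15, seed = 1) {
  if (sensitivity_permil_per_100mm >= 0)
    stop("sensitivity must be negative (proxy sign convention)", call. = FALSE)
  set.seed(.sub_seed(seed, 2L))
  d <- baseline_permil +
    sensitivity_permil_per_100mm * (rain$value - mean(rain$value)) / 100 +
    stats::rnorm(nrow(rain), sd = noise_sd_permil)
  data.frame(year = rain$year, value = d)
}

#' Simulate one tree core from a true signal
#'
#' Samples are laid down at constant calendar spacing `1/growth_rate` from the
#' youngest year of the span inward; calendar years inside an optional hiatus
#' window yield no samples. Sample numbers count from the bark (youngest = 1).
#' The measured delta 13C is the signal interpolated at the sample's true year
#' plus Gaussian measurement noise.
#'
#' @param true_signal data frame (`year`, `value`) from [rainfall_to_d13c()].
#' @param growth_rate_samples_per_year radial sampling rate (default 0.63,
#'   which turns a ~700-year lifespan into ~450 samples).
#' @param hiatus optional `c(start_CE, end_CE)` window with no preserved
#'   growth.
#' @param measurement_noise_sd per-sample noise in per mille (default 0.1).
#' @param tree_id core label.
#' @param seed integer seed.
#' @return list with `series` (an [isotope_series()]) and `true_ages` (data
#'   frame `sample_number`, `year`).
#' @export
simulate_tree <- function(true_signal, growth_rate_samples_per_year = 0.63,
                          hiatus = NULL, measurement_noise_sd = 0.1,
                          tree_id = "SYN", seed = 1) {
  if (growth_rate_samples_per_year <= 0)
    stop("growth rate must be > 0", call. = FALSE)
  y_min <- min(true_signal$year); y_max <- max(true_signal$year)
  if (!is.null(hiatus)) {
    if (hiatus[1] <= y_min && hiatus[2] >= y_max)
      stop("hiatus covers the whole span", call. = FALSE)
  }
  yrs <- rev(seq(y_max, y_min, by = -1 / growth_rate_samples_per_year))
  if (!is.null(hiatus))
    yrs <- yrs[yrs < hiatus[1] | yrs > hiatus[2]]
  yrs <- sort(yrs, decreasing = TRUE)    # sample 1 = youngest
  set.seed(.sub_seed(seed, 3L))
  sig <- stats::approx(true_signal$year, true_signal$value, xout = yrs)$y
  d13c <- sig + stats::rnorm(length(yrs), sd = measurement_noise_sd)
  series <- isotope_series(tree_id, seq_along(yrs), d13c)
  list(series = series,
       true_ages = data.frame(sample_number = seq_along(yrs), year = yrs))
}

#' Synthetic radiocarbon calibration curve
#'
#' Pre-bomb segment: `14C age = slope * calBP + wiggle`, a smooth sinusoidal
#' wiggle superimposed on a linear relation (the default amplitude and period
#' give 1-sigma calibrated intervals a few decades wide). If `bomb = TRUE`, a
#' post-bomb F14C segment is also returned: a sharp rise to a mid-1960s peak
#' followed by a quasi-exponential decline, so some F14C values are crossed
#' twice and calibrate to two disjoint intervals.
#'
#' @param span `c(first_year, last_year)` CE that the curve must cover.
#' @param slope 14C years per calendar year (default 1), must be positive.
#' @param wiggle_amp_14Cyr,wiggle_period_yr wiggle amplitude and period.
#' @param curve_sigma one-sigma curve uncertainty in 14C years (default 10).
#' @param bomb also build the post-1950 F14C segment.
#' @param seed integer seed (sets the wiggle phase).
#' @return list with `prebomb` (and, if requested, `postbomb`)
#'   [calibration_curve()] objects.
#' @export
synth_calibration_curve <- function(span = c(1300, 2015), slope = 1,
                                    wiggle_amp_14Cyr = 20,
                                    wiggle_period_yr = 150,
                                    curve_sigma = 10, bomb = FALSE, seed = 1) {
  if (slope <= 0) stop("slope must be positive", call. = FALSE)
  set.seed(.sub_seed(seed, 4L))
  phase <- stats::runif(1, 0, 2 * pi)
  bp <- seq(ce_to_bp(min(1949, span[2]) + 1), ce_to_bp(span[1]) + 10)
  mu <- slope * bp + wiggle_amp_14Cyr * sin(2 * pi * bp / wiggle_period_yr + phase)
  pre <- calibration_curve(bp, mu, rep(curve_sigma, length(bp)),
                           era = "pre_bomb")
  out <- list(prebomb = pre)
  if (bomb) {
    ce <- 1950:max(2020, span[2] + 5)
    peak <- 1964
    f14c <- ifelse(ce <= peak,
                   1 + 0.8 * (ce - 1950) / (peak - 1950),
                   1.05 + 0.75 * exp(-(ce - peak) / 16))
    out$postbomb <- calibration_curve(ce_to_bp(ce), f14c,
                                      rep(0.004, length(ce)),
                                      era = "post_bomb_F14C")
  }
  out
}

#' Simulate AMS radiocarbon dates along a core
#'
#' Dated sample numbers are spread evenly over the core, always including both
#' ends. Pre-1950 samples yield conventional 14C ages (curve mean at the true
#' age plus Gaussian lab error); post-1950 samples yield F14C measurements
#' against the bomb curve. With `outlier_rate > 0`, each simulated set swaps
#' the true ages of one pair of dated samples with that probability,
#' emulating a sample mislabeling, and marks both dates `flagged_outlier`.
#'
#' @param true_ages data frame (`sample_number`, `year`) from
#'   [simulate_tree()].
#' @param curves list from [synth_calibration_curve()] (with `postbomb` when
#'   the core reaches past 1950).
#' @param n_dates number of dates (default 13, the order used on real cores).
#' @param lab_sigma lab error for conventional ages, 14C years (default 25).
#' @param lab_sigma_f14c lab error on the F14C scale (default 0.005).
#' @param outlier_rate probability of injecting one mislabeled pair.
#' @param tree_id core label.
#' @param seed integer seed.
#' @return a [radiocarbon_dates()] table; the injected swap (if any) is
#'   recorded in the `"swapped_samples"` attribute.
#' @export
simulate_radiocarbon_dates <- function(true_ages, curves, n_dates = 13,
                                       lab_sigma = 25, lab_sigma_f14c = 0.005,
                                       outlier_rate = 0, tree_id = "SYN",
                                       seed = 1) {
  if (n_dates < 2) stop("need n_dates >= 2", call. = FALSE)
  if (n_dates > nrow(true_ages))
    stop("n_dates exceeds the number of samples", call. = FALSE)
  set.seed(.sub_seed(seed, 5L))
  idx <- unique(round(seq(1, nrow(true_ages), length.out = n_dates)))
  sn <- true_ages$sample_number[idx]
  yr <- true_ages$year[idx]
  swapped <- NULL
  flagged <- rep(FALSE, length(idx))
  if (outlier_rate > 0 && length(idx) >= 2 &&
      stats::runif(1) < outlier_rate) {
    pick <- sample(length(idx), 2)
    yr[pick] <- yr[rev(pick)]
    swapped <- sn[pick]
    flagged[pick] <- TRUE
  }
  rows <- lapply(seq_along(idx), function(i) {
    if (yr[i] >= 1950) {
      if (is.null(curves$postbomb))
        stop("post-1950 sample but no bomb curve supplied", call. = FALSE)
      at <- curve_at(curves$postbomb, ce_to_bp(yr[i]))
      data.frame(tree_id = tree_id, sample_number = sn[i],
                 measurement_type = "F14C",
                 value = at$mu + stats::rnorm(1, sd = lab_sigma_f14c),
                 sigma = lab_sigma_f14c, flagged_outlier = flagged[i])
    } else {
      at <- curve_at(curves$prebomb, ce_to_bp(yr[i]))
      data.frame(tree_id = tree_id, sample_number = sn[i],
                 measurement_type = "conventional_BP",
                 value = at$mu + stats::rnorm(1, sd = lab_sigma),
                 sigma = lab_sigma, flagged_outlier = flagged[i])
    }
  })
  out <- radiocarbon_dates(do.call(rbind, rows))
  attr(out, "swapped_samples") <- swapped
  out
}

#' Simulate atmospheric delta 13C and CO2 records
#'
#' Both records are flat at their pre-industrial values before 1850 and follow
#' a smooth, monotone (quadratic-in-time) decline/rise afterwards, emulating
#' the Suess-effect depletion of atmospheric delta 13C and the industrial CO2
#' increase.
#'
#' @param span `c(first_year, last_year)` CE; must include 1748.
#' @param preindustrial_d13c pre-industrial atmospheric delta 13C (default
#'   -6.3 per mille).
#' @param suess_decline_permil total post-1850 decline (default -2.0).
#' @param co2_pre,co2_modern pre-industrial and end-of-span CO2 (ppm).
#' @param industrial_onset_CE year the records start moving (default 1850).
#' @return list with `atm` and `co2` [annual_record()]s.
#' @export
simulate_atm_records <- function(span = c(1300, 2015),
                                 preindustrial_d13c = -6.3,
                                 suess_decline_permil = -2.0,
                                 co2_pre = 280, co2_modern = 400,
                                 industrial_onset_CE = 1850) {
  if (span[1] > 1748 || span[2] < 1748)
    stop("span must include the 1748 reference year", call. = FALSE)
  years <- span[1]:span[2]
  s <- pmax(0, (years - industrial_onset_CE) /
              (span[2] - industrial_onset_CE))^2
  list(atm = annual_record(years, preindustrial_d13c + suess_decline_permil * s,
                           kind = "d13c_atm", max_gap = 1),
       co2 = annual_record(years, co2_pre + (co2_modern - co2_pre) * s,
                           kind = "co2", max_gap = 1))
}

#' Exact tie points of a simulated tree
#'
#' Builds the tie-point table an analyst would supply: the outermost and
#' innermost dated samples plus, for a hiatus tree, the duplicate-sample pair
#' carrying the stop and resume years.
#'
#' @param tree a [simulate_tree()] result.
#' @param tree_id label for the table.
#' @param jitter_years optional uniform jitter (half-width, years) applied to
#'   interior knot years, for age-model error studies.
#' @param seed integer seed used when `jitter_years > 0`.
#' @return a [tie_points()] table.
#' @export
true_tie_points <- function(tree, tree_id = tree$series$tree_id,
                            jitter_years = 0, seed = 1) {
  ta <- tree$true_ages
  n <- nrow(ta)
  rows <- data.frame(tree_id = tree_id,
                     sample_number = c(ta$sample_number[1], ta$sample_number[n]),
                     year_CE = c(ta$year[1], ta$year[n]))
  gaps <- diff(ta$year)            # negative steps; a hiatus is a big drop
  spacing <- stats::median(abs(gaps))
  h <- which(-gaps > 5 * spacing)
  if (length(h) == 1L) {
    ## the hiatus ring carries two ages (younger listed first): the outer
    ## segment's constant growth extended one sample inward (resume side) and
    ## the true age of the first post-hiatus sample (stop side)
    rows <- rbind(rows,
                  data.frame(tree_id = tree_id,
                             sample_number = rep(ta$sample_number[h + 1], 2),
                             year_CE = c(ta$year[h] - spacing, ta$year[h + 1])))
  }
  if (jitter_years > 0) {
    set.seed(.sub_seed(seed, 6L))
    rows$year_CE <- rows$year_CE +
      stats::runif(nrow(rows), -jitter_years, jitter_years)
  }
  tie_points(rows)
}

#' Simulate a complete multi-tree study
#'
#' Orchestrates the whole generator: regional rainfall, the true delta 13C
#' signal, several trees (by default four, spanning 1300-2015 CE, one with a
#' 1500-1700 growth hiatus, with sampling rates that yield 430-710 samples per
#' core and 12-15 radiocarbon dates each), the calibration curves, the
#' atmospheric records, and two forcing indices (one tied to rainfall, one
#' independent AR(1)). Everything regenerates bit-identically from
#' `(seed, arguments)`.
#'
#' @param seed integer master seed.
#' @param span study window, years CE.
#' @param tree_configs list of per-tree lists with elements `tree_id`,
#'   `growth_rate`, `hiatus` (or `NULL`), `n_dates`.
#' @param rain_args,signal_args optional argument lists overriding
#'   [generate_rainfall()] / [rainfall_to_d13c()] defaults.
#' @param measurement_noise_sd per-sample measurement noise (per mille).
#' @param outlier_rate passed to [simulate_radiocarbon_dates()].
#' @return a `synthetic_world` list: `rainfall`, `signal` (the plant signal,
#'   the recovery target), `ring_signal` (signal plus the atmospheric Suess
#'   imprint, what the rings record), `trees` (each with `series`,
#'   `true_ages`, `dates`, `tie_points`), `curves`, `atm`, `co2`, `forcing`
#'   (named list of annual records), `seed`, `span`.
#' @export
simulate_world <- function(seed = 1, span = c(1300, 2015),
                           tree_configs = default_tree_configs(),
                           rain_args = list(), signal_args = list(),
                           measurement_noise_sd = 0.1, outlier_rate = 0) {
  rainfall <- do.call(generate_rainfall,
                      c(list(span = span, seed = seed), rain_args))
  signal <- do.call(rainfall_to_d13c,
                    c(list(rain = rainfall, seed = seed), signal_args))
  curves <- synth_calibration_curve(span = span, bomb = TRUE, seed = seed)
  records <- simulate_atm_records(span = span)
  ## rings record the plant signal plus the atmospheric delta 13C anomaly
  ## relative to the pre-industrial reference (the Suess-effect imprint that
  ## suess_correct() is designed to remove)
  atm_ref <- records$atm$value[records$atm$year == 1748]
  ring_signal <- signal
  ring_signal$value <- signal$value +
    (records$atm$value[match(signal$year, records$atm$year)] - atm_ref)
  trees <- lapply(seq_along(tree_configs), function(i) {
    cfg <- tree_configs[[i]]
    tr <- simulate_tree(ring_signal,
                        growth_rate_samples_per_year = cfg$growth_rate,
                        hiatus = cfg$hiatus,
                        measurement_noise_sd = measurement_noise_sd,
                        tree_id = cfg$tree_id,
                        seed = seed * 10L + i)
    tr$dates <- simulate_radiocarbon_dates(
      tr$true_ages, curves, n_dates = cfg$n_dates,
      outlier_rate = outlier_rate, tree_id = cfg$tree_id,
      seed = seed * 10L + i)
    tr$tie_points <- true_tie_points(tr)
    tr
  })
  names(trees) <- vapply(tree_configs, `[[`, "", "tree_id")
  years <- rainfall$year
  set.seed(.sub_seed(seed, 7L))
  wet_index <- -scale(moving_average(rainfall$value, 11))[, 1] +
    stats::rnorm(length(years), sd = 0.5)
  indep <- as.numeric(stats::arima.sim(list(ar = 0.7), n = length(years)))
  forcing <- list(
    sst_like = annual_record(years, wet_index, kind = "forcing_index"),
    pdo_like = annual_record(years, indep, kind = "forcing_index"))
  structure(list(rainfall = rainfall, signal = signal,
                 ring_signal = ring_signal, trees = trees,
                 curves = curves, atm = records$atm, co2 = records$co2,
                 forcing = forcing, seed = seed, span = span),
            class = "synthetic_world")
}

#' Default tree configurations for [simulate_world()]
#'
#' Four cores patterned on a real north-south transect: three slower-growing
#' trees (~450 samples over ~700 years) one of which has a 1500-1700 CE
#' hiatus, and one faster-growing tree (~700 samples), with 12-15 radiocarbon
#' dates each.
#'
#' @return list of per-tree configuration lists.
#' @export
default_tree_configs <- function() {
  list(list(tree_id = "T1", growth_rate = 0.61, hiatus = NULL, n_dates = 12),
       list(tree_id = "T2", growth_rate = 0.63, hiatus = NULL, n_dates = 12),
       list(tree_id = "T3", growth_rate = 0.64, hiatus = c(1500, 1700),
            n_dates = 13),
       list(tree_id = "T4", growth_rate = 0.99, hiatus = NULL, n_dates = 15))
}
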