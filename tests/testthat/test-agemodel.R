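test_that("two-segment model reproduces printed tie-point arithmetic", {
  m <- fit_age_model(dfl_tie_points())
  expect_equal(nrow(m$knots), 3)
  expect_null(m$hiatus)
  # midpoint of the first linear segment
  expect_equal(age_at(m, 137.5), 1815.0)
  # growth rate of segment 1: (2005 - 1625) / (265 - 10) years per sample
  rate <- (age_at(m, 10) - age_at(m, 11)) * 1
  expect_equal(rate, (2005 - 1625) / (265 - 10), tolerance = 1e-12)
  expect_equal(rate, 1.490, tolerance = 1e-3)
  expect_error(age_at(m, 5), "outside age-model domain")
  expect_equal(age_at(m, 5, extrapolate = TRUE), 2005)
})

test_that("a duplicate-sample tie pair becomes a 250-year hiatus", {
  m <- fit_age_model(gtr_tie_points())
  expect_equal(m$hiatus$sample_number, 380)
  expect_equal(m$hiatus$year_resume_CE - m$hiatus$year_stop_CE, 250)
  # outer segment ends at the resume year, inner starts at the stop year
  expect_equal(age_at(m, 379.999), 1750, tolerance = 1e-2)
  expect_equal(age_at(m, 380), 1500)
  # no assigned year falls inside the open hiatus window
  s <- isotope_series("GTR", 18:450, rep(-25, 433))
  dated <- suppressMessages(assign_ages(m, s))
  expect_false(any(dated$year > 1500 & dated$year < 1750))
})

test_that("age model fitting validates its inputs", {
  expect_error(fit_age_model(data.frame(tree_id = "A", sample_number = 1,
                                        year_CE = 2000)),
               "at least 2")
  expect_error(fit_age_model(data.frame(tree_id = "A",
                                        sample_number = c(1, 100),
                                        year_CE = c(1500, 1900))),
               "inversion")
  # equal years at distinct samples: not strictly decreasing
  expect_error(fit_age_model(data.frame(tree_id = "A",
                                        sample_number = c(1, 50, 100),
                                        year_CE = c(2000, 1900, 1900))),
               "strictly decrease")
})

test_that("model year strictly decreases with sample number (hiatus jump included)", {
  for (tp in list(dfl_tie_points(), gtr_tie_points())) {
    m <- fit_age_model(tp)
    s <- seq(m$domain[1], m$domain[2], by = 0.5)
    y <- age_at(m, s)
    expect_true(all(diff(y) < 0))
  }
})

test_that("refitting tie points extracted from a model reproduces it exactly", {
  m <- fit_age_model(gtr_tie_points())
  tp2 <- data.frame(tree_id = "GTR", sample_number = m$knots$sample_number,
                    year_CE = m$knots$year_CE)
  m2 <- fit_age_model(tp2)
  expect_equal(m2$knots, m$knots)
  expect_equal(m2$hiatus, m$hiatus)
  s <- seq(18, 450, by = 7)
  expect_equal(age_at(m2, s), age_at(m, s))
})

test_that("exact tie points recover true ages exactly; jittered ones within 5 years", {
  w <- suppressMessages(simulate_world(seed = 3))
  for (nm in c("T1", "T4")) {  # linear-growth trees
    tr <- w$trees[[nm]]
    m <- fit_age_model(tr$tie_points)
    dated_years <- age_at(m, tr$true_ages$sample_number)
    expect_equal(dated_years, tr$true_ages$year, tolerance = 1e-9)
  }
  # hiatus tree: exact except possibly at the hiatus ring itself
  tr <- w$trees$T3
  m <- fit_age_model(tr$tie_points)
  err <- abs(age_at(m, tr$true_ages$sample_number) - tr$true_ages$year)
  expect_equal(mean(err), 0, tolerance = 1e-9)

  # +/- 5-year tie-point jitter keeps mean absolute age error within 5 years
  for (s in 1:5) {
    tr <- w$trees$T2
    tp <- true_tie_points(tr, jitter_years = 5, seed = s)
    mj <- fit_age_model(tp)
    errs <- abs(age_at(mj, tr$true_ages$sample_number, extrapolate = TRUE) -
                  tr$true_ages$year)
    expect_lte(mean(errs), 5)
  }
})

test_that("validation reports interval membership and distances", {
  cc <- identity_curve(sigma = 0)
  m <- fit_age_model(data.frame(tree_id = "T", sample_number = c(1, 400),
                                year_CE = c(1900, 1300)))
  mk_date <- function(sn, bp) {
    cd <- calibrate(rc_date(bp, 20, sample_number = sn), cc)
    cd
  }
  # date centred on the model year at sample 200 (1600 CE = 350 BP)
  good <- mk_date(200, 350)
  # date 100 years off
  bad <- mk_date(200, 450)
  rep <- suppressMessages(validate_model(m, list(good, bad)))
  expect_true(rep$dates$inside_1sigma[1])
  expect_false(rep$dates$inside_1sigma[2])
  expect_equal(rep$dates$distance_to_nearest_interval[1], 0)
  # distance = gap between model year 1600 and the interval around 1500
  expect_equal(rep$dates$distance_to_nearest_interval[2], 100 - 20, tolerance = 2)
  expect_equal(rep$summary$fraction_inside, 0.5)
  # flagged outliers are reported but not counted
  bad_flagged <- calibrate(rc_date(450, 20, sample_number = 200, flagged = TRUE), cc)
  rep2 <- suppressMessages(validate_model(m, list(good, bad_flagged)))
  expect_equal(rep2$summary$n_checked, 1)
  expect_equal(rep2$summary$fraction_inside, 1)
  expect_error(validate_model(m, list()), "no calibrated dates")
})

test_that("true-model validation achieves roughly nominal 1-sigma coverage", {
  # many synthetic dates on one long linear-growth tree; the true age model
  # should land inside the 68.3% interval at close to the nominal rate
  set.seed(21)
  cc <- identity_curve(sigma = 10)
  m <- fit_age_model(data.frame(tree_id = "T", sample_number = c(1, 700),
                                year_CE = c(1949, 1250)))
  n <- 250
  sn <- sample(1:700, n, replace = TRUE)
  truth <- age_at(m, sn)
  inside <- vapply(seq_len(n), function(i) {
    meas <- ce_to_bp(truth[i]) + rnorm(1, sd = sqrt(25^2 + 10^2))
    cd <- calibrate(rc_date(meas, 25, sample_number = sn[i]), cc)
    any(truth[i] >= cd$hpd_intervals$start_CE - 0.5 &
        truth[i] <= cd$hpd_intervals$end_CE + 0.5)
  }, logical(1))
  expect_gt(mean(inside), 0.60)
  expect_lt(mean(inside), 0.78)
})

test_that("stratigraphic inversions are flagged if and only if present", {
  cc <- identity_curve(sigma = 0)
  d1 <- calibrate(rc_date(200, 25, sample_number = 10), cc)  # ~1750 CE
  d2 <- calibrate(rc_date(230, 25, sample_number = 50), cc)  # overlapping, older
  expect_equal(nrow(detect_inversions(list(d1, d2))), 0)

  # disjoint intervals in reversed stratigraphic order
  d3 <- calibrate(rc_date(500, 25, sample_number = 10), cc)  # shallow but old
  d4 <- calibrate(rc_date(200, 25, sample_number = 50), cc)
  flags <- detect_inversions(list(d3, d4))
  expect_equal(nrow(flags), 1)
  expect_equal(flags$sample_number_young, 10)
  expect_equal(flags$sample_number_old, 50)
})

test_that("an injected mislabeled date pair is detected as an inversion", {
  w <- suppressMessages(simulate_world(seed = 8, outlier_rate = 1))
  swapped <- lapply(w$trees, function(tr) attr(tr$dates, "swapped_samples"))
  has_swap <- !vapply(swapped, is.null, logical(1))
  expect_true(any(has_swap))
  nm <- names(which(has_swap))[1]
  tr <- w$trees[[nm]]
  cal <- calibrate_dates(tr$dates, w$curves$prebomb, w$curves$postbomb)
  flags <- detect_inversions(cal)
  expect_gt(nrow(flags), 0)
  flagged_samples <- unique(c(flags$sample_number_young, flags$sample_number_old))
  expect_true(all(sort(swapped[[nm]]) %in% sort(flagged_samples)) ||
                any(swapped[[nm]] %in% flagged_samples))
})
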