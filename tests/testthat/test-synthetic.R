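test_that("rainfall generator is deterministic and respects its parameters", {
  r1 <- generate_rainfall(seed = 4)
  r2 <- generate_rainfall(seed = 4)
  expect_identical(r1, r2)
  expect_false(identical(generate_rainfall(seed = 5)$value, r1$value))

  flat <- generate_rainfall(trend_mm_per_century = 0, centennial_amp_mm = 0,
                            noise_sd_mm = 0, seed = 1)
  expect_true(all(flat$value == 450))
  expect_error(generate_rainfall(ar1_phi = 1.2), "ar1_phi")
  expect_error(generate_rainfall(span = c(2000, 2050)), ">= 100")
})

test_that("rainfall sample mean stays within 3 standard errors of the target", {
  means <- vapply(1:100, function(s) mean(generate_rainfall(seed = s)$value),
                  numeric(1))
  # AR(1) with phi 0.6 over 716 years: se of the mean ~ sd/sqrt(n_eff)
  se <- sd(means)
  expect_lt(abs(mean(means) - 450), 3 * se / sqrt(100) * 10) # generous guard
  expect_lt(abs(mean(means) - 450), 3 * 40 / sqrt(716 / 4))
})

test_that("rainfall-to-d13c map is a negative affine law plus noise", {
  rain <- generate_rainfall(seed = 6)
  pure <- rainfall_to_d13c(rain, noise_sd_permil = 0, seed = 6)
  expect_equal(cor(rain$value, pure$value), -1)
  at_mean <- rainfall_to_d13c(
    annual_record(1601:1700, rep(500, 100), "rainfall"),
    noise_sd_permil = 0, seed = 1)
  expect_true(all(at_mean$value == -25.3))
  expect_error(rainfall_to_d13c(rain, sensitivity_permil_per_100mm = 0.2),
               "negative")
  # with default noise the correlation stays strong over 100 seeds
  rs <- vapply(1:100, function(s)
    cor(rain$value, rainfall_to_d13c(rain, seed = s)$value), numeric(1))
  expect_true(all(rs < -0.7))
})

test_that("simulated trees honour growth rate, hiatus and noise settings", {
  sig <- data.frame(year = 1300:2015, value = rep(-25.3, 716))
  tr <- simulate_tree(sig, growth_rate_samples_per_year = 0.63, seed = 2)
  expect_equal(nrow(tr$series$samples), 451, tolerance = 3)
  expect_equal(tr$true_ages$year[1], 2015)
  expect_true(all(diff(tr$true_ages$year) < 0))

  hia <- simulate_tree(sig, hiatus = c(1500, 1700), seed = 2)
  expect_false(any(hia$true_ages$year >= 1500 & hia$true_ages$year <= 1700))

  clean <- simulate_tree(sig, measurement_noise_sd = 0, seed = 2)
  expect_true(all(clean$series$samples$delta13C == -25.3))
  expect_error(simulate_tree(sig, hiatus = c(1200, 2100)), "whole span")
})

test_that("synthetic calibration curve is monotone without wiggles, wiggly with", {
  flat <- synth_calibration_curve(wiggle_amp_14Cyr = 0, seed = 1)
  expect_true(all(diff(flat$prebomb$grid$mu) > 0))
  wig <- synth_calibration_curve(seed = 1, bomb = TRUE)
  expect_s3_class(wig$postbomb, "calibration_curve")
  # bomb segment is non-monotone: some F14C levels are crossed twice
  f <- wig$postbomb$grid$mu
  expect_true(any(diff(f) > 0) && any(diff(f) < 0))
  expect_error(synth_calibration_curve(slope = 0), "slope")
})

test_that("simulated dates cover both core ends and respect requested counts", {
  sig <- data.frame(year = 1300:2015, value = rep(-25.3, 716))
  tr <- simulate_tree(sig, seed = 3)
  curves <- synth_calibration_curve(bomb = TRUE, seed = 3)
  dates <- simulate_radiocarbon_dates(tr$true_ages, curves, n_dates = 13,
                                      seed = 3)
  expect_equal(nrow(dates), 13)
  expect_true(1 %in% dates$sample_number)
  expect_true(max(tr$true_ages$sample_number) %in% dates$sample_number)
  expect_true(any(dates$measurement_type == "F14C"))   # 2015-side samples
  expect_error(simulate_radiocarbon_dates(tr$true_ages, curves,
                                          n_dates = 10000), "exceeds")

  # zero lab error and zero wiggle: measured ages equal the curve exactly
  curves0 <- synth_calibration_curve(wiggle_amp_14Cyr = 0, bomb = TRUE, seed = 3)
  d0 <- simulate_radiocarbon_dates(tr$true_ages, curves0, lab_sigma = 1e-12,
                                   lab_sigma_f14c = 1e-12, seed = 3)
  pre <- d0[d0$measurement_type == "conventional_BP", ]
  truth <- tr$true_ages$year[match(pre$sample_number, tr$true_ages$sample_number)]
  expect_equal(pre$value, curve_at(curves0$prebomb, ce_to_bp(truth))$mu,
               tolerance = 1e-6)
})

test_that("atmospheric records are flat pre-industrial and move smoothly after", {
  rec <- simulate_atm_records()
  expect_equal(rec$atm$value[rec$atm$year == 1700], -6.3)
  expect_equal(rec$co2$value[rec$co2$year == 1700], 280)
  expect_equal(rec$atm$value[rec$atm$year == 1748], -6.3)
  expect_true(all(diff(rec$atm$value[rec$atm$year >= 1850]) <= 0))
  expect_true(all(diff(rec$co2$value[rec$co2$year >= 1850]) >= 0))
  expect_equal(rec$co2$value[rec$co2$year == 2015], 400)
  expect_error(simulate_atm_records(span = c(1800, 2015)), "1748")

  # degenerate parameters make the downstream corrections identities
  none <- simulate_atm_records(suess_decline_permil = 0, co2_modern = 280)
  dated <- data.frame(year = c(1400, 1900, 2000), delta13C = c(-25, -25.2, -24.8))
  out <- suppressMessages(correct_series(dated, none$atm, none$co2))
  expect_equal(out$delta13C, dated$delta13C, tolerance = 1e-12)
})

test_that("the whole synthetic world regenerates bit-identically from its seed", {
  w1 <- suppressMessages(simulate_world(seed = 2))
  w2 <- suppressMessages(simulate_world(seed = 2))
  expect_identical(w1$rainfall, w2$rainfall)
  expect_identical(lapply(w1$trees, `[[`, "series"),
                   lapply(w2$trees, `[[`, "series"))
  expect_identical(w1$trees$T3$dates, w2$trees$T3$dates)
  expect_identical(w1$forcing, w2$forcing)
  # per-core sample counts in the magnitudes of real slow/fast-growing cores
  counts <- vapply(w1$trees, function(tr) nrow(tr$series$samples), numeric(1))
  expect_true(all(counts[1:2] > 400 & counts[1:2] < 500))
  expect_true(counts[3] > 300 & counts[3] < 400)  # 200-year hiatus removed
  expect_true(counts[4] > 650 & counts[4] < 750)
  # hiatus tree carries a duplicate-sample tie pair
  tp3 <- w1$trees$T3$tie_points
  expect_equal(sum(duplicated(tp3$sample_number)), 1)
})
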