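# Independent fine-grid oracle: evaluates the same Gaussian likelihood with
# its own interpolation, normalizes by trapezoidal integration on a 0.05-year
# grid, and reports the probability mass attached to each integer year.
oracle_density <- function(value, sigma, curve, step = 0.05) {
  g <- curve$grid
  ce_fine <- seq(ceiling(1950 - max(g$cal_BP)), floor(1950 - min(g$cal_BP)),
                 by = step)
  mu <- approx(1950 - g$cal_BP, g$mu, xout = ce_fine)$y
  sg <- approx(1950 - g$cal_BP, g$sigma, xout = ce_fine)$y
  lik <- dnorm(value, mu, sqrt(sigma^2 + sg^2))
  z <- sum((lik[-1] + lik[-length(lik)]) / 2) * step  # trapezoid
  yrs <- ce_fine[ce_fine == round(ce_fine)]
  data.frame(year_CE = yrs, prob = lik[ce_fine == round(ce_fine)] / z * 1)
}

test_that("calibrated density is normalized with its mode at the curve preimage", {
  cc <- identity_curve(sigma = 0)
  cd <- calibrate(rc_date(500, 1), cc)
  expect_equal(sum(cd$density$prob), 1, tolerance = 1e-9)
  expect_equal(cd$density$year_CE[which.max(cd$density$prob)], 1950 - 500)

  # monotone synthetic curve: measurement equal to mu(Y) puts the mode at Y
  bp <- 0:800
  wig <- calibration_curve(bp, bp + 15 * sin(bp / 40), rep(5, 801), "pre_bomb")
  Y <- 1950 - 300
  mu_Y <- curve_at(wig, 300)$mu
  cd2 <- calibrate(rc_date(mu_Y, 0.5), wig)
  expect_equal(cd2$density$year_CE[which.max(cd2$density$prob)], Y)
})

test_that("68.3% HPD of 500 +/- 30 BP on the identity curve is the Gaussian 1-sigma band", {
  # oracle: numerical integration of a N(500, 30) density over the annual grid
  # gives mass 0.683 within about +/- 30.3 years of the mean
  cc <- identity_curve(sigma = 0)
  cd <- calibrate(rc_date(500, 30), cc)
  iv <- cd$hpd_intervals
  expect_equal(nrow(iv), 1)
  expect_equal(iv$start_CE, 1950 - 530, tolerance = 0.004)
  expect_equal(iv$end_CE, 1950 - 470, tolerance = 0.004)
  expect_gte(iv$mass, 0.683)
})

test_that("calibration matches the fine-grid numerical oracle", {
  set.seed(11)
  bp <- 0:900
  curve <- calibration_curve(bp, bp + 20 * sin(2 * pi * bp / 150),
                             rep(10, length(bp)), era = "pre_bomb")
  for (i in 1:20) {
    val <- runif(1, 100, 800)
    sig <- runif(1, 15, 40)
    cd <- calibrate(rc_date(val, sig), curve)
    orc <- oracle_density(val, sig, curve)
    m <- merge(cd$density, orc, by = "year_CE")
    tv <- 0.5 * sum(abs(m$prob.x - m$prob.y / sum(m$prob.y)))
    expect_lt(tv, 1e-6)
  }
})

test_that("post-bomb F14C calibration handles multimodality and symmetry", {
  # rise-and-fall bomb curve: values on both limbs calibrate to two intervals
  ce <- 1950:2015
  f14 <- ifelse(ce <= 1964, 1 + 0.8 * (ce - 1950) / 14,
                1.8 - 0.75 * (ce - 1964) / 51)
  bomb <- calibration_curve(1950 - ce, f14, rep(0.001, length(ce)),
                            era = "post_bomb_F14C")
  cd <- calibrate_postbomb(rc_date(1.4, 0.004, type = "F14C"), bomb)
  expect_equal(nrow(cd$hpd_intervals), 2)
  expect_gt(cd$hpd_intervals$start_CE[2], cd$hpd_intervals$end_CE[1]) # disjoint, sorted
  expect_true(all(cd$hpd_intervals$end_CE >= cd$hpd_intervals$start_CE))

  # value at the unique maximum with tiny sigma: single narrow interval
  cd2 <- calibrate_postbomb(rc_date(1.8, 0.002, type = "F14C"), bomb)
  expect_equal(nrow(cd2$hpd_intervals), 1)
  expect_true(cd2$hpd_intervals$start_CE <= 1964 && 1964 <= cd2$hpd_intervals$end_CE)

  # symmetric tent curve: density symmetric about the peak year
  ce_s <- 1950:1978
  tent <- calibration_curve(1950 - ce_s, 1.8 - abs(ce_s - 1964) * 0.05,
                            rep(0.001, length(ce_s)), era = "post_bomb_F14C")
  cd3 <- calibrate_postbomb(rc_date(1.5, 0.01, type = "F14C"), tent)
  d <- cd3$density
  left <- d$prob[match(1964 - 1:13, d$year_CE)]
  right <- d$prob[match(1964 + 1:13, d$year_CE)]
  expect_equal(left, right, tolerance = 1e-9)
})

test_that("HPD selection is minimal, handles ties and multimodality", {
  # uniform density over 10 years at 0.683 coverage: 7 grid years required
  u <- data.frame(year_CE = 2001:2010, prob = rep(0.1, 10))
  iv <- hpd(u, 0.683)
  expect_equal(sum(iv$end_CE - iv$start_CE + 1), 7)
  expect_gte(sum(iv$mass), 0.683)

  # unimodal density: single interval containing the mode
  g <- data.frame(year_CE = 1900:2000, prob = dnorm(1900:2000, 1950, 10))
  g$prob <- g$prob / sum(g$prob)
  iv2 <- hpd(g, 0.683)
  expect_equal(nrow(iv2), 1)
  expect_true(iv2$start_CE <= 1950 && 1950 <= iv2$end_CE)

  # bimodal equal peaks: two intervals; with a coverage consuming whole tie
  # groups the two intervals carry equal mass by symmetry
  b <- data.frame(year_CE = 1:20,
                  prob = dnorm(1:20, 5, 1.2) + dnorm(1:20, 15, 1.2))
  b$prob <- b$prob / sum(b$prob)
  iv3 <- hpd(b, 0.70)
  expect_equal(nrow(iv3), 2)
  expect_equal(iv3$mass[1], iv3$mass[2], tolerance = 1e-12)

  expect_error(hpd(u, 1.2), "coverage")
})

test_that("HPD equals a brute-force probability-ranked subset oracle on small grids", {
  set.seed(7)
  for (rep in 1:5) {
    p <- runif(20)
    p <- p / sum(p)
    d <- data.frame(year_CE = 101:120, prob = p)
    iv <- hpd(d, 0.683)
    # oracle: take grid years by descending probability until mass reached
    ord <- order(-p, d$year_CE)
    k <- which(cumsum(p[ord]) >= 0.683)[1]
    sel <- sort(d$year_CE[ord[1:k]])
    got <- unlist(lapply(seq_len(nrow(iv)), function(i)
      iv$start_CE[i]:iv$end_CE[i]))
    expect_equal(got, sel)
  }
})

test_that("calibration is shift-equivariant and errors outside curve support", {
  bp <- 0:500
  cc <- calibration_curve(bp, bp + 10 * sin(bp / 25), rep(8, 501), "pre_bomb")
  cd <- calibrate(rc_date(250, 20), cc)
  k <- 40
  cc_k <- calibration_curve(bp + k, bp + 10 * sin(bp / 25) + k, rep(8, 501),
                            "pre_bomb")
  cd_k <- calibrate(rc_date(250 + k, 20), cc_k)
  shifted <- transform(cd_k$density, year_CE = year_CE + k)
  m <- merge(cd$density, shifted, by = "year_CE")
  expect_equal(nrow(m), nrow(cd$density))
  expect_equal(m$prob.x, m$prob.y, tolerance = 1e-9)

  expect_error(calibrate(rc_date(5000, 10), cc), "zero total")
})
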