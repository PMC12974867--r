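# Shared fixtures, built in code. Oracles that cross-check full algorithms
# live next to the tests that use them.

# identity calibration curve: mu(theta) = theta cal BP, sigma = 0 (or given)
identity_curve <- function(bp_min = -100, bp_max = 1200, sigma = 0) {
  bp <- bp_min:bp_max
  calibration_curve(bp, bp, rep(sigma, length(bp)), era = "pre_bomb")
}

# one-row radiocarbon date
rc_date <- function(value, sigma, type = "conventional_BP", tree_id = "T",
                    sample_number = 1, flagged = FALSE) {
  data.frame(tree_id = tree_id, sample_number = sample_number,
             measurement_type = type, value = value, sigma = sigma,
             flagged_outlier = flagged)
}

# tie points patterned on a real slow-growing core: two linear segments
dfl_tie_points <- function() {
  tie_points(data.frame(tree_id = "DFL",
                        sample_number = c(10, 265, 450),
                        year_CE = c(2005, 1625, 1280)))
}

# tie points with a growth hiatus: ring 380 carries 1750 and 1500 CE
gtr_tie_points <- function() {
  tie_points(data.frame(tree_id = "GTR",
                        sample_number = c(18, 380, 380, 450),
                        year_CE = c(2015, 1750, 1500, 1340)))
}

# constant atmospheric / CO2 records over a span
constant_atm <- function(span = c(1300, 2015), d13c = -6.3) {
  annual_record(span[1]:span[2], rep(d13c, diff(span) + 1), kind = "d13c_atm")
}
constant_co2 <- function(span = c(1300, 2015), ppm = 280) {
  annual_record(span[1]:span[2], rep(ppm, diff(span) + 1), kind = "co2")
}
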