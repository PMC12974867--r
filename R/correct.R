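## Atmospheric and physiological corrections of ring delta 13C. Two effects
## contaminate the plant water-stress signal after industrialisation: the
## Suess effect (fossil-fuel CO2 lowers atmospheric delta 13C) and the plant's
## response to rising CO2 concentration itself (changing ci/ca and hence
## photosynthetic discrimination). Both are removed relative to a
## pre-industrial reference year, 1748 by default.

#' Delta notation from isotope ratios
#'
#' delta13C = (R_sample / R_standard - 1) * 1000, in per mille relative to the
#' standard (VPDB for carbon).
#'
#' @param R_sample,R_standard isotope ratios (13C/12C), both `> 0`.
#' @return per-mille delta value.
#' @export
delta_from_ratio <- function(R_sample, R_standard) {
  if (any(R_sample <= 0) || any(R_standard <= 0))
    stop("isotope ratios must be > 0", call. = FALSE)
  (R_sample / R_standard - 1) * 1000
}

#' @rdname delta_from_ratio
#' @param delta per-mille delta value.
#' @return `ratio_from_delta()` returns the sample ratio implied by a delta
#'   value and the standard's ratio.
#' @export
ratio_from_delta <- function(delta, R_standard) {
  if (any(R_standard <= 0)) stop("isotope ratios must be > 0", call. = FALSE)
  (delta / 1000 + 1) * R_standard
}

## linear interpolation of an annual record at (possibly fractional) years;
## outside the record span is an error
.annual_at <- function(record, years, what = "annual record") {
  rng <- range(record$year)
  if (any(years < rng[1] | years > rng[2]))
    stop(sprintf("year %.1f outside %s span [%d, %d]",
                 years[which(years < rng[1] | years > rng[2])[1]],
                 what, rng[1], rng[2]), call. = FALSE)
  stats::approx(record$year, record$value, xout = years)$y
}

#' Suess-effect correction of a dated series
#'
#' Removes the atmospheric delta 13C anomaly relative to a pre-industrial
#' reference year: `delta_corr(t) = delta(t) - (d13c_atm(t) -
#' d13c_atm(ref_year))`. Samples at or before the reference year are unchanged
#' whenever the atmospheric record is constant up to that year.
#'
#' @param dated data frame with columns `year` (CE, fractional allowed) and
#'   `delta13C`.
#' @param atm an [annual_record()] of kind `"d13c_atm"` covering every sample
#'   year (fractional years are linearly interpolated).
#' @param ref_year pre-industrial reference year CE (default 1748, the
#'   inflection between pre- and post-industrial atmospheric change).
#' @return the dated series with `delta13C` replaced by corrected values.
#' @export
suess_correct <- function(dated, atm, ref_year = 1748) {
  stopifnot(is.data.frame(dated), all(c("year", "delta13C") %in% names(dated)))
  if (ref_year < min(atm$year) || ref_year > max(atm$year))
    stop("ref_year outside atmospheric record span", call. = FALSE)
  anom <- .annual_at(atm, dated$year, "d13c_atm record") -
    .annual_at(atm, ref_year, "d13c_atm record")
  out <- dated
  out$delta13C <- dated$delta13C - anom
  .log_msg("correct", "suess: %d samples, max |anomaly| %.3f permil",
           nrow(out), max(abs(anom)))
  out
}

#' Parameters of the pre-industrial (pin) correction
#'
#' @param ref_year_CE pre-industrial reference year (default 1748).
#' @param a_diffusion per-mille fractionation by diffusion through stomata
#'   (default 4.4).
#' @param b_carboxylation per-mille fractionation by carboxylation
#'   (default 27.0). Must exceed `a_diffusion`.
#' @param response_mode how the plant is assumed to respond to rising CO2:
#'   `"constant_ci_offset"` (default) keeps the drawdown `ca - ci` constant,
#'   floored at the constant-ci/ca projection; `"constant_ci_ca"` keeps the
#'   ratio ci/ca constant (under which discrimination, and hence the
#'   correction, is unchanged). The two modes bracket observed plant
#'   behaviour.
#' @return a `pin_parameters` list.
#' @export
pin_parameters <- function(ref_year_CE = 1748, a_diffusion = 4.4,
                           b_carboxylation = 27.0,
                           response_mode = c("constant_ci_offset",
                                             "constant_ci_ca")) {
  response_mode <- match.arg(response_mode)
  if (b_carboxylation <= a_diffusion)
    stop("b_carboxylation must exceed a_diffusion", call. = FALSE)
  structure(list(ref_year_CE = ref_year_CE, a_diffusion = a_diffusion,
                 b_carboxylation = b_carboxylation,
                 response_mode = response_mode),
            class = "pin_parameters")
}

#' Pre-industrial (pin) correction for plant response to rising CO2
#'
#' Applied after [suess_correct()]. For each sample year after the reference
#' year the observed discrimination is converted to a leaf-internal CO2
#' concentration, the plant state is mapped back to the pre-industrial
#' atmosphere under the configured response mode, and the discrimination is
#' re-expressed as a delta 13C value at the reference-year atmosphere:
#'
#' * `Delta(t) = (d13c_atm(ref) - delta(t)) / (1 + delta(t)/1000)`
#' * `ci(t) = ca(t) * (Delta(t) - a) / (b - a)`
#' * `constant_ci_offset`: `ci_pin = ci - (ca(t) - ca(ref))`, floored at the
#'   constant-ci/ca projection `ci * ca(ref) / ca(t)`
#' * `constant_ci_ca`: `ci_pin = ci * ca(ref) / ca(t)` (identity overall)
#' * `Delta_pin = a + (b - a) * ci_pin / ca(ref)` and
#'   `delta_pin = (d13c_atm(ref) - Delta_pin) / (1 + Delta_pin/1000)`
#'
#' Years at or before the reference year are returned unchanged.
#'
#' @param dated Suess-corrected dated series (`year`, `delta13C`).
#' @param atm atmospheric delta 13C [annual_record()] (only its reference-year
#'   value enters, the Suess normalisation having removed the time variation).
#' @param co2 CO2 concentration [annual_record()] (ppm) covering all years.
#' @param params a [pin_parameters()] list.
#' @return the dated series with corrected `delta13C`.
#' @export
pin_correct <- function(dated, atm, co2, params = pin_parameters()) {
  stopifnot(inherits(params, "pin_parameters"))
  a <- params$a_diffusion; b <- params$b_carboxylation
  ref <- params$ref_year_CE
  if (ref < min(atm$year) || ref > max(atm$year) ||
      ref < min(co2$year) || ref > max(co2$year))
    stop("ref_year outside atmospheric/CO2 record span", call. = FALSE)
  atm_ref <- .annual_at(atm, ref, "d13c_atm record")
  ca_ref <- .annual_at(co2, ref, "co2 record")
  post <- dated$year > ref
  out <- dated
  if (!any(post)) return(out)
  d <- dated$delta13C[post]
  ca_t <- .annual_at(co2, dated$year[post], "co2 record")
  Delta <- (atm_ref - d) / (1 + d / 1000)
  ci <- ca_t * (Delta - a) / (b - a)
  ci_pin <- switch(params$response_mode,
    constant_ci_ca = ci * ca_ref / ca_t,
    constant_ci_offset = pmax(ci - (ca_t - ca_ref), ci * ca_ref / ca_t))
  if (any(ci_pin <= 0))
    stop("pin correction produced ci <= 0: implausible inputs", call. = FALSE)
  Delta_pin <- a + (b - a) * ci_pin / ca_ref
  out$delta13C[post] <- (atm_ref - Delta_pin) / (1 + Delta_pin / 1000)
  .log_msg("correct", "pin (%s): %d post-%d samples, max |shift| %.3f permil",
           params$response_mode, sum(post), ref,
           max(abs(out$delta13C[post] - dated$delta13C[post])))
  out
}

#' Full atmospheric correction of a dated series
#'
#' Convenience wrapper: [suess_correct()] followed by [pin_correct()], the
#' order in which the corrections are defined.
#'
#' @inheritParams pin_correct
#' @inheritParams suess_correct
#' @return corrected dated series.
#' @export
correct_series <- function(dated, atm, co2, params = pin_parameters()) {
  pin_correct(suess_correct(dated, atm, ref_year = params$ref_year_CE),
              atm, co2, params)
}
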