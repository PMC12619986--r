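#' Fit an H2O2 fluorescence calibration line
#'
#' Ordinary least-squares line of fluorescence on known H2O2 concentration,
#' from a daily calibration series recorded without tissue. The gain (slope,
#' fluorescence units per pmol/mL) converts fluorescence slopes of sample
#' traces into H2O2 concentration rates.
#'
#' @param series Data frame with columns `conc` (pmol/mL) and `fluor`
#'   (fluorescence units); at least two distinct concentrations.
#' @return Object of class `"h2o2_calibration"`: `gain`, `offset`,
#'   `r_squared`, `n_points`. A non-positive fitted gain triggers a warning
#'   (the calibration is not usable for rate conversion).
#' @examples
#' fit_calibration(generate_calibration_series(0:7 * 50, gain = 2, offset = 10))
#' @export
fit_calibration <- function(series) {
  check_columns(series, c("conc", "fluor"), "`series`")
  conc <- series$conc; fl <- series$fluor
  if (length(conc) < 2 || length(unique(conc)) < 2)
    stop("calibration needs at least 2 distinct concentrations", call. = FALSE)
  gain <- ls_slope(conc, fl)
  offset <- mean(fl) - gain * mean(conc)
  fitted <- offset + gain * conc
  tss <- sum((fl - mean(fl))^2)
  r2 <- if (tss > 0) 1 - sum((fl - fitted)^2) / tss else 1
  if (gain <= 0) warning("fitted calibration gain is not positive")
  structure(list(gain = gain, offset = offset, r_squared = r2,
                 n_points = length(conc)),
            class = "h2o2_calibration")
}

#' @export
print.h2o2_calibration <- function(x, ...) {
  cat(sprintf("H2O2 calibration: gain %.4g au per pmol/mL, offset %.4g au (n = %d, R2 = %.4f)\n",
              x$gain, x$offset, x$n_points, x$r_squared))
  invisible(x)
}

#' Per-state H2O2 emission rates from a fluorescence trace
#'
#' Convenience wrapper around [extract_state_rates()] returning only the
#' calibrated H2O2 emission rates (pmol min^-1 mg^-1 wet mass) over the
#' same per-state steady-state windows used for respiration.
#'
#' @inheritParams extract_state_rates
#' @param cal A [fit_calibration()] result with positive gain.
#' @return Named numeric vector of per-state H2O2 emission rates.
#' @export
h2o2_rates <- function(trace, cal, window_s = 60, settle_s = 60) {
  if (missing(cal) || !inherits(cal, "h2o2_calibration"))
    stop("a fitted `h2o2_calibration` is required", call. = FALSE)
  tab <- extract_state_rates(trace, window_s = window_s, settle_s = settle_s,
                             cal = cal)
  stats::setNames(tab$h2o2_rate, tab$state)
}

#' Free radical leak
#'
#' The H2O2 emission rate divided by the simultaneous O2 consumption rate,
#' an index of the fraction of electron flow leaking to superoxide/H2O2.
#' By study convention both rates are taken in the glutamate + malate +
#' ADP + succinate state. The default is the plain ratio in pmol H2O2 per
#' nmol O2; `mode = "electron_pair_percent"` instead expresses it as
#' `100 * H2O2 / (2 * O2)` with both rates in the same molar unit
#' (accounting for the two electrons transferred per O2 reduced), i.e.
#' `100 * h2o2_rate / (2 * 1000 * o2_flux)` with the units used here.
#'
#' @param h2o2_rate H2O2 emission rate, pmol min^-1 mg^-1.
#' @param o2_flux O2 consumption rate, nmol min^-1 mg^-1; must be positive.
#' @param mode `"ratio"` (default) or `"electron_pair_percent"`.
#' @return Leak value (vectorized); `NA` with a warning where `o2_flux <= 0`.
#' @examples
#' free_radical_leak(10, 5)   # 2 pmol H2O2 per nmol O2
#' @export
free_radical_leak <- function(h2o2_rate, o2_flux,
                              mode = c("ratio", "electron_pair_percent")) {
  mode <- match.arg(mode)
  bad <- !is.finite(o2_flux) | o2_flux <= 0
  if (any(bad)) warning("non-positive O2 flux; free radical leak undefined there")
  out <- ifelse(bad, NA_real_,
                if (mode == "ratio") h2o2_rate / o2_flux
                else 100 * h2o2_rate / (2 * 1000 * o2_flux))
  unname(out)
}

#' Normalize H2O2 emission rates by an OXPHOS protein content index
#'
#' @param rates Numeric vector of H2O2 emission rates (or a rate table with
#'   an `h2o2_rate` column).
#' @param oxphos_index Positive scalar index for this sample.
#' @return Rates divided by the index (same shape as the input).
#' @export
normalize_h2o2_by_index <- function(rates, oxphos_index) {
  check_positive_scalar(oxphos_index, "oxphos_index")
  if (is.data.frame(rates)) {
    check_columns(rates, "h2o2_rate", "`rates`")
    rates$h2o2_rate <- rates$h2o2_rate / oxphos_index
    rates
  } else {
    rates / oxphos_index
  }
}
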