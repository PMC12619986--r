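#' Specification of a synthetic oxygraph/fluorimeter trace
#'
#' Describes an event-annotated substrate-uncoupler-inhibitor titration
#' (SUIT) run in a closed 2-chamber respirometer: each protocol row opens a
#' respiratory state with a true oxygen flux (nmol O2 min^-1 mg^-1 wet mass)
#' and a true H2O2 emission rate (pmol min^-1 mg^-1). Within a state the
#' chamber O2 concentration falls linearly at rate `flux * wet_mass /
#' chamber_volume` and the resorufin-type fluorescence rises linearly at a
#' rate set by the H2O2 emission and the fluorophore gain; additive Gaussian
#' noise is applied to both channels.
#'
#' @param protocol Data frame with columns `label`, `time_s`, `o2_flux`,
#'   `h2o2_rate`; event times must be strictly increasing and the state
#'   opened by row k lasts until row k+1 (the last state until
#'   `end_time_s`). See [suit_protocol()] for the default five-state run.
#' @param wet_mass_mg Wet mass of the permeabilized fiber bundle in mg
#'   (typical bundles weigh 3-6 mg).
#' @param chamber_volume_mL Chamber volume in mL (default 2).
#' @param o2_start Initial O2 concentration, nmol/mL.
#' @param fluor_gain Fluorescence units per (pmol H2O2 / mL); links the
#'   generated fluorescence slope to the generating H2O2 rate and should
#'   match the gain of the calibration series analysed alongside the trace.
#' @param noise_sd Additive Gaussian noise SD applied to both channels
#'   (signal units).
#' @param sampling_interval_s Sampling interval in seconds.
#' @param end_time_s End of recording; defaults to 300 s after the last event.
#' @param seed Integer seed or `NULL`.
#'
#' @return An object of class `"trace_spec"`.
#' @export
trace_spec <- function(protocol = suit_protocol(),
                       wet_mass_mg = 4, chamber_volume_mL = 2,
                       o2_start = 600, fluor_gain = 1,
                       noise_sd = 0, sampling_interval_s = 2,
                       end_time_s = NULL, seed = NULL) {
  check_columns(protocol, c("label", "time_s", "o2_flux", "h2o2_rate"),
                "`protocol`")
  if (nrow(protocol) < 1) stop("`protocol` must have at least one event", call. = FALSE)
  if (any(duplicated(protocol$time_s)))
    stop("protocol events overlap: event times must be distinct", call. = FALSE)
  if (is.unsorted(protocol$time_s, strictly = TRUE))
    stop("protocol event times must be strictly increasing", call. = FALSE)
  check_positive_scalar(wet_mass_mg, "wet_mass_mg")
  check_positive_scalar(chamber_volume_mL, "chamber_volume_mL")
  check_positive_scalar(fluor_gain, "fluor_gain")
  check_positive_scalar(sampling_interval_s, "sampling_interval_s")
  if (!is_scalar_number(noise_sd) || noise_sd < 0)
    stop("`noise_sd` must be a single non-negative number", call. = FALSE)
  if (is.null(end_time_s)) end_time_s <- max(protocol$time_s) + 300
  if (end_time_s <= max(protocol$time_s))
    stop("`end_time_s` must lie after the last event", call. = FALSE)
  structure(
    list(protocol = as.data.frame(protocol), wet_mass_mg = wet_mass_mg,
         chamber_volume_mL = chamber_volume_mL, o2_start = o2_start,
         fluor_gain = fluor_gain, noise_sd = noise_sd,
         sampling_interval_s = sampling_interval_s,
         end_time_s = end_time_s, seed = seed),
    class = "trace_spec")
}

#' Default SUIT titration protocol
#'
#' Five-state substrate-uncoupler-inhibitor titration used throughout:
#' glutamate + malate (GM, state II), + ADP (state III), + succinate (SUCC,
#' state III with convergent Complex I+II input), + oligomycin (OLI, leak),
#' + antimycin A (AA, residual non-mitochondrial consumption).
#'
#' @param o2_fluxes,h2o2_rates Named numeric vectors (names `GM`, `ADP`,
#'   `SUCC`, `OLI`, `AA`) of true per-state O2 fluxes
#'   (nmol min^-1 mg^-1) and H2O2 emission rates (pmol min^-1 mg^-1).
#' @param state_duration_s Length of each state in seconds.
#' @return Protocol data frame for [trace_spec()].
#' @export
suit_protocol <- function(o2_fluxes = c(GM = 5, ADP = 15, SUCC = 25,
                                        OLI = 6, AA = 2),
                          h2o2_rates = c(GM = 8, ADP = 5, SUCC = 12,
                                         OLI = 20, AA = 3),
                          state_duration_s = 300) {
  states <- names(o2_fluxes)
  stopifnot(!is.null(states), identical(states, names(h2o2_rates)))
  data.frame(label = states,
             time_s = state_duration_s * (seq_along(states) - 1),
             o2_flux = as.numeric(o2_fluxes),
             h2o2_rate = as.numeric(h2o2_rates),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic annotated respirometry trace
#'
#' Realizes a [trace_spec()] as an event-annotated time series of chamber O2
#' concentration and H2O2-probe fluorescence. Noiseless traces are exactly
#' piecewise linear: within a state the O2 slope is
#' `-o2_flux * wet_mass_mg / chamber_volume_mL / 60` nmol mL^-1 s^-1 and the
#' fluorescence slope is
#' `fluor_gain * h2o2_rate * wet_mass_mg / chamber_volume_mL / 60` per
#' second.
#'
#' @param spec A [trace_spec()].
#' @return An object of class `"annotated_trace"`: list with `time`
#'   (seconds), `o2_conc` (nmol/mL), `fluor` (arbitrary units), `events`
#'   (data frame `label`, `time_s`), `chamber_volume_mL`, `wet_mass_mg`.
#' @examples
#' tr <- generate_trace(trace_spec(noise_sd = 0.2, seed = 7))
#' plot(tr)
#' @export
generate_trace <- function(spec) {
  stopifnot(inherits(spec, "trace_spec"))
  pr <- spec$protocol
  time <- seq(min(pr$time_s), spec$end_time_s, by = spec$sampling_interval_s)
  state <- findInterval(time, pr$time_s)
  # cumulative piecewise-linear integration of the per-state slopes
  o2_slope <- -pr$o2_flux * spec$wet_mass_mg / spec$chamber_volume_mL / 60
  fl_slope <- spec$fluor_gain * pr$h2o2_rate * spec$wet_mass_mg /
    spec$chamber_volume_mL / 60
  seg_value <- function(slopes) {
    bounds <- c(pr$time_s, spec$end_time_s)
    seg_len <- diff(bounds)
    start_val <- cumsum(c(0, slopes * seg_len))[seq_len(nrow(pr))]
    start_val[state] + slopes[state] * (time - pr$time_s[state])
  }
  o2 <- spec$o2_start + seg_value(o2_slope)
  fl <- seg_value(fl_slope)
  if (spec$noise_sd > 0) {
    noise <- with_seed(spec$seed, stats::rnorm(2 * length(time), 0, spec$noise_sd))
    o2 <- o2 + noise[seq_along(time)]
    fl <- fl + noise[length(time) + seq_along(time)]
  }
  structure(
    list(time = time, o2_conc = o2, fluor = fl,
         events = pr[, c("label", "time_s")],
         chamber_volume_mL = spec$chamber_volume_mL,
         wet_mass_mg = spec$wet_mass_mg),
    class = "annotated_trace")
}

#' @export
print.annotated_trace <- function(x, ...) {
  cat("Annotated respirometry trace\n")
  cat(sprintf("  %d samples over %.0f s; chamber %.2g mL, bundle %.2g mg\n",
              length(x$time), diff(range(x$time)),
              x$chamber_volume_mL, x$wet_mass_mg))
  cat("  events:", paste(sprintf("%s@%gs", x$events$label, x$events$time_s),
                         collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.annotated_trace <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$time, x$o2_conc, type = "l", xlab = "time (s)",
                 ylab = "O2 (nmol/mL)", ...)
  graphics::abline(v = x$events$time_s, lty = 3, col = "grey40")
  graphics::mtext(x$events$label, side = 3, at = x$events$time_s,
                  cex = 0.7, line = 0)
  graphics::plot(x$time, x$fluor, type = "l", xlab = "time (s)",
                 ylab = "fluorescence (au)", ...)
  graphics::abline(v = x$events$time_s, lty = 3, col = "grey40")
  invisible(x)
}

#' Generate a synthetic H2O2 calibration series
#'
#' Emulates the daily calibration of the Amplex UltraRed-horseradish
#' peroxidase system by successive additions of known H2O2 concentrations in
#' the absence of tissue: fluorescence responds linearly,
#' `fluor = offset + gain * conc + noise`.
#'
#' @param known_concs Numeric vector (length >= 2, at least two distinct
#'   values) of H2O2 concentrations, pmol/mL.
#' @param gain Fluorescence units per pmol/mL.
#' @param offset Baseline fluorescence.
#' @param noise_sd Additive Gaussian noise SD (fluorescence units).
#' @param seed Integer seed or `NULL`.
#' @return Data frame with columns `conc`, `fluor`.
#' @seealso [fit_calibration()]
#' @export
generate_calibration_series <- function(known_concs, gain = 1, offset = 0,
                                        noise_sd = 0, seed = NULL) {
  if (length(known_concs) < 2 || length(unique(known_concs)) < 2)
    stop("calibration needs at least 2 distinct H2O2 concentrations",
         call. = FALSE)
  if (!is_scalar_number(noise_sd) || noise_sd < 0)
    stop("`noise_sd` must be a single non-negative number", call. = FALSE)
  fl <- offset + gain * known_concs
  if (noise_sd > 0)
    fl <- fl + with_seed(seed, stats::rnorm(length(known_concs), 0, noise_sd))
  data.frame(conc = as.numeric(known_concs), fluor = fl)
}
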