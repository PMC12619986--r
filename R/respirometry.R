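#' Extract per-state rates from an annotated respirometry trace
#'
#' Turns an event-annotated oxygraph trace into a per-state rate table. Each
#' titration event opens a state lasting until the next event (the last
#' until the end of the recording). Within each state a fixed trailing
#' steady-state window is used: the last `window_s` seconds of the state,
#' after discarding `settle_s` seconds of mixing/settling following the
#' addition. The O2 flux is the negative least-squares slope of O2
#' concentration over the window, scaled to the bundle:
#' `flux = -slope * chamber_volume_mL / wet_mass_mg * 60`
#' in nmol O2 min^-1 mg^-1 wet mass. When a calibration is supplied and the
#' trace carries a fluorescence channel, the H2O2 emission rate over the
#' same window is `(fluor slope / gain) * chamber_volume_mL / wet_mass_mg *
#' 60`, in pmol min^-1 mg^-1.
#'
#' States too short for settle + window are not dropped: the available data
#' after the settle time are used and the state is QC-flagged
#' `"short_state"`; a state with fewer than 2 usable samples yields `NA`
#' rates and flag `"too_few_samples"`.
#'
#' @param trace An `"annotated_trace"` (see [generate_trace()] or
#'   [read_trace()]).
#' @param window_s Trailing steady-state window length, seconds (default 60).
#' @param settle_s Settle time discarded after each addition, seconds
#'   (default 60).
#' @param cal Optional [fit_calibration()] result; enables `h2o2_rate`.
#' @param aa_correct If `TRUE`, subtract the antimycin-A (`AA`) state O2
#'   flux — residual non-mitochondrial consumption — from all other states.
#'   Default `FALSE`: the AA state is reported as its own condition.
#'
#' @return Object of class `"state_rate_table"`: data frame with columns
#'   `state`, `o2_flux`, `h2o2_rate` (if calibrated), `window_start`,
#'   `window_end`, `n_points`, `qc`.
#' @examples
#' tr <- generate_trace(trace_spec(seed = 1))
#' extract_state_rates(tr)
#' @export
extract_state_rates <- function(trace, window_s = 60, settle_s = 60,
                                cal = NULL, aa_correct = FALSE) {
  stopifnot(inherits(trace, "annotated_trace"))
  check_positive_scalar(window_s, "window_s")
  if (!is_scalar_number(settle_s) || settle_s < 0)
    stop("`settle_s` must be a single non-negative number", call. = FALSE)
  if (is.unsorted(trace$time, strictly = TRUE))
    stop("trace time must be strictly increasing", call. = FALSE)
  if (!is.null(cal)) {
    stopifnot(inherits(cal, "h2o2_calibration"))
    if (cal$gain <= 0) stop("calibration gain must be positive", call. = FALSE)
    if (is.null(trace$fluor))
      stop("trace has no fluorescence channel", call. = FALSE)
  }

  ev <- trace$events
  bounds <- c(ev$time_s, max(trace$time))
  scale <- trace$chamber_volume_mL / trace$wet_mass_mg * 60

  rows <- lapply(seq_len(nrow(ev)), function(k) {
    t0 <- bounds[k]; t1 <- bounds[k + 1]
    qc <- character(0)
    w_start <- max(t1 - window_s, t0 + settle_s)
    if (t1 - t0 < settle_s + window_s) qc <- c(qc, "short_state")
    sel <- trace$time >= w_start & trace$time <= t1
    n_pts <- sum(sel)
    if (n_pts < 2) {
      return(data.frame(state = ev$label[k], o2_flux = NA_real_,
                        h2o2_rate = if (is.null(cal)) NULL else NA_real_,
                        window_start = w_start, window_end = t1,
                        n_points = n_pts,
                        qc = paste(c(qc, "too_few_samples"), collapse = ";"),
                        stringsAsFactors = FALSE))
    }
    tt <- trace$time[sel]
    o2_slope <- ls_slope(tt, trace$o2_conc[sel])
    out <- data.frame(state = ev$label[k], o2_flux = -o2_slope * scale,
                      stringsAsFactors = FALSE)
    if (!is.null(cal))
      out$h2o2_rate <- ls_slope(tt, trace$fluor[sel]) / cal$gain * scale
    out$window_start <- w_start; out$window_end <- t1
    out$n_points <- n_pts
    out$qc <- paste(qc, collapse = ";")
    out
  })
  tab <- do.call(rbind, rows)

  if (aa_correct) {
    aa <- tab$o2_flux[tab$state == "AA"]
    if (length(aa) != 1 || !is.finite(aa))
      stop("`aa_correct = TRUE` requires a usable AA state", call. = FALSE)
    other <- tab$state != "AA"
    tab$o2_flux[other] <- tab$o2_flux[other] - aa
  }
  class(tab) <- c("state_rate_table", "data.frame")
  attr(tab, "wet_mass_mg") <- trace$wet_mass_mg
  attr(tab, "chamber_volume_mL") <- trace$chamber_volume_mL
  tab
}

# least-squares slope of y on t
ls_slope <- function(t, y) {
  tc <- t - mean(t)
  sum(tc * (y - mean(y))) / sum(tc^2)
}

#' Acceptor control ratio (ACR)
#'
#' Index of mitochondrial coupling efficiency: the maximal ADP-stimulated
#' (state III, glutamate + malate + ADP) respiration rate divided by the
#' substrate-only (state II, glutamate + malate) rate.
#'
#' @param state_rates A [extract_state_rates()] table containing states
#'   `GM` (state II) and `ADP` (state III).
#' @param state_ii,state_iii State labels to use, defaults `"GM"`, `"ADP"`.
#' @return Dimensionless ratio; `NA` with a warning when the state II flux
#'   is not positive.
#' @export
acr <- function(state_rates, state_ii = "GM", state_iii = "ADP") {
  check_columns(state_rates, c("state", "o2_flux"), "`state_rates`")
  get1 <- function(s) {
    v <- state_rates$o2_flux[state_rates$state == s]
    if (length(v) != 1) stop("state `", s, "` not found exactly once", call. = FALSE)
    v
  }
  ii <- get1(state_ii); iii <- get1(state_iii)
  if (!is.finite(ii) || ii <= 0) {
    warning("state II flux is not positive; ACR undefined")
    return(NA_real_)
  }
  iii / ii
}

#' Normalize respiration rates by an OXPHOS protein content index
#'
#' Divides every O2 flux by a per-sample OXPHOS protein content index (see
#' [oxphos_index()]), expressing respiration per unit of OXPHOS protein
#' rather than per mg of wet mass.
#'
#' @param state_rates A [extract_state_rates()] table.
#' @param oxphos_index Positive scalar index for this sample.
#' @return The table with `o2_flux` divided by the index.
#' @export
normalize_by_oxphos_index <- function(state_rates, oxphos_index) {
  check_columns(state_rates, "o2_flux", "`state_rates`")
  check_positive_scalar(oxphos_index, "oxphos_index")
  state_rates$o2_flux <- state_rates$o2_flux / oxphos_index
  state_rates
}

#' Average duplicate respirometry runs of the same sample
#'
#' Per-state arithmetic mean of two technical replicate rate tables.
#' States whose duplicates differ by more than `tol` (relative to their
#' mean) are QC-flagged `"duplicates_discordant"`, not dropped.
#'
#' @param a,b Two [extract_state_rates()] tables over the same states (same
#'   order).
#' @param tol Relative-difference flag threshold, default 0.2 (20%).
#' @return A rate table of the same shape with averaged `o2_flux` (and
#'   `h2o2_rate` when present in both).
#' @export
average_duplicates <- function(a, b, tol = 0.2) {
  check_columns(a, c("state", "o2_flux"), "`a`")
  check_columns(b, c("state", "o2_flux"), "`b`")
  if (!identical(as.character(a$state), as.character(b$state)))
    stop("duplicate runs have mismatched states", call. = FALSE)
  out <- a
  spread <- abs(a$o2_flux - b$o2_flux) /
    pmax(abs(a$o2_flux + b$o2_flux) / 2, .Machine$double.eps)
  out$o2_flux <- (a$o2_flux + b$o2_flux) / 2
  if (!is.null(a$h2o2_rate) && !is.null(b$h2o2_rate))
    out$h2o2_rate <- (a$h2o2_rate + b$h2o2_rate) / 2
  flag <- !is.na(spread) & spread > tol
  if (!is.null(out$qc)) {
    out$qc[flag] <- sub("^;", "", paste(out$qc[flag], "duplicates_discordant",
                                        sep = ";"))
  } else {
    out$qc <- ifelse(flag, "duplicates_discordant", "")
  }
  out
}
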