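#' Write an annotated trace to CSV plus a JSON event sidecar
#'
#' The time series goes to a long-format CSV with columns `time_s`,
#' `o2_nmol_per_ml`, `fluor_au`; the titration events, chamber volume and
#' bundle wet mass go to a JSON sidecar so the trace is fully
#' reconstructable from plain text.
#'
#' @param trace An `"annotated_trace"`.
#' @param csv_path,events_path Output file paths.
#' @return Invisibly, the two paths.
#' @export
write_trace <- function(trace, csv_path, events_path) {
  stopifnot(inherits(trace, "annotated_trace"))
  utils::write.csv(
    data.frame(time_s = trace$time, o2_nmol_per_ml = trace$o2_conc,
               fluor_au = trace$fluor),
    csv_path, row.names = FALSE)
  jsonlite::write_json(
    list(events = trace$events,
         chamber_volume_mL = trace$chamber_volume_mL,
         wet_mass_mg = trace$wet_mass_mg),
    events_path, auto_unbox = TRUE, digits = NA)
  invisible(c(csv_path, events_path))
}

#' Read an annotated trace from CSV plus its JSON event sidecar
#'
#' @param csv_path,events_path Paths written by [write_trace()].
#' @return An `"annotated_trace"`.
#' @export
read_trace <- function(csv_path, events_path) {
  ts <- utils::read.csv(csv_path)
  check_columns(ts, c("time_s", "o2_nmol_per_ml"), "trace CSV")
  side <- jsonlite::read_json(events_path, simplifyVector = TRUE)
  ev <- as.data.frame(side$events)
  check_columns(ev, c("label", "time_s"), "event sidecar")
  structure(
    list(time = ts$time_s, o2_conc = ts$o2_nmol_per_ml,
         fluor = ts$fluor_au,
         events = ev[order(ev$time_s), c("label", "time_s")],
         chamber_volume_mL = side$chamber_volume_mL,
         wet_mass_mg = side$wet_mass_mg),
    class = "annotated_trace")
}
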