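#' Generate a synthetic per-fiber histology table
#'
#' Emulates per-fiber integrity calls made on laminin-DAPI and
#' NCAM-dystrophin stained cross-sections: independent Bernoulli flags for
#' NCAM positivity (denervation marker), at least one central nucleus, a
#' nuclear clump (aggregation of two or more nuclei) and damaged laminin,
#' plus a log-normal cross-sectional area (CSA). NCAM+ fibers have their CSA
#' scaled by `ncam_csa_ratio`, emulating the atrophy of denervated fibers;
#' the expected CSA contrast of NCAM+ vs NCAM- fibers is
#' `100 * (ncam_csa_ratio - 1)` percent.
#'
#' @param n_fibers Number of fibers (>= 1).
#' @param marker_probs Named probabilities in `[0, 1]` for `ncam_pos`,
#'   `central_nucleus`, `nuclear_clump`, `damaged_laminin`.
#' @param csa_mean,csa_sd Mean and SD of CSA in square micrometres (the
#'   log-normal draw is parameterized to match them for NCAM- fibers).
#' @param ncam_csa_ratio Multiplicative CSA factor for NCAM+ fibers; the
#'   default 0.822 emulates a -17.8% contrast.
#' @param participant,timepoint Labels copied onto every row.
#' @param seed Integer seed or `NULL`.
#'
#' @return Data frame with columns `participant`, `timepoint`, `ncam_pos`,
#'   `central_nucleus`, `nuclear_clump`, `damaged_laminin` (logical) and
#'   `csa` (numeric, > 0).
#' @export
generate_histology_table <- function(n_fibers,
                                     marker_probs = c(ncam_pos = 0.02,
                                                      central_nucleus = 0.05,
                                                      nuclear_clump = 0.02,
                                                      damaged_laminin = 0.03),
                                     csa_mean = 4500, csa_sd = 1500,
                                     ncam_csa_ratio = 0.822,
                                     participant = "P1", timepoint = "pre",
                                     seed = NULL) {
  if (!is_scalar_number(n_fibers) || n_fibers < 1 || n_fibers != round(n_fibers))
    stop("`n_fibers` must be a positive integer", call. = FALSE)
  markers <- c("ncam_pos", "central_nucleus", "nuclear_clump", "damaged_laminin")
  if (!all(markers %in% names(marker_probs)))
    stop("`marker_probs` must be named with: ", paste(markers, collapse = ", "),
         call. = FALSE)
  for (m in markers) check_fraction(marker_probs[[m]], m)
  check_positive_scalar(csa_mean, "csa_mean")
  check_positive_scalar(csa_sd, "csa_sd")
  check_positive_scalar(ncam_csa_ratio, "ncam_csa_ratio")

  with_seed(seed, {
    flags <- lapply(markers, function(m)
      stats::runif(n_fibers) < marker_probs[[m]])
    names(flags) <- markers
    cv <- csa_sd / csa_mean
    sdlog <- sqrt(log(1 + cv^2))
    meanlog <- log(csa_mean) - sdlog^2 / 2
    csa <- stats::rlnorm(n_fibers, meanlog, sdlog)
    csa[flags$ncam_pos] <- csa[flags$ncam_pos] * ncam_csa_ratio
    data.frame(participant = participant, timepoint = timepoint,
               ncam_pos = flags$ncam_pos,
               central_nucleus = flags$central_nucleus,
               nuclear_clump = flags$nuclear_clump,
               damaged_laminin = flags$damaged_laminin,
               csa = csa, stringsAsFactors = FALSE)
  })
}
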