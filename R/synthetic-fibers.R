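#' Specification of a synthetic single-fiber QIF population
#'
#' Describes the generative model for a section's worth of per-fiber
#' quadruple-immunofluorescence (QIF) measurements: a mitochondrial mass
#' marker (VDAC1) and two OXPHOS subunit channels (NDUFB8 for Complex I,
#' MT-CO1 for Complex IV). Control fibers follow a linear relationship
#' between transformed subunit intensity and transformed mass-marker
#' intensity; a stated fraction of fibers is shifted below (deficient) or
#' above (overabundant) that line.
#'
#' Intensities are generated on the log2 scale by default, mirroring how the
#' downstream prediction-interval model is fitted; `transform = "none"`
#' generates the same linear structure on the raw scale.
#'
#' @param n_fibers Number of fibers in the section (positive integer).
#' @param mass_mean,mass_sd Location and scale of the mass-marker intensity
#'   on the generating (transformed) scale.
#' @param slope,intercept Control relationship of subunit signal on mass
#'   signal (transformed scale).
#' @param resid_sd Residual standard deviation about the control line
#'   (transformed scale); must be non-negative.
#' @param frac_low,frac_high Fractions in `[0, 1]` of deficient and
#'   overabundant fibers; their sum must not exceed 1.
#' @param low_shift,high_shift Signed offsets (transformed-scale units)
#'   applied to deficient (must be `<= 0`) and overabundant (`>= 0`) fibers.
#' @param transform `"log2"` (default) or `"none"`: scale on which the linear
#'   relationship holds and on which shifts are expressed.
#' @param seed Integer seed for reproducible generation, or `NULL`.
#'
#' @return An object of class `"fiber_population_spec"`.
#' @seealso [generate_fiber_population()]
#' @export
fiber_population_spec <- function(n_fibers,
                                  mass_mean = 10, mass_sd = 0.6,
                                  slope = 1, intercept = 0,
                                  resid_sd = 0.25,
                                  frac_low = 0, frac_high = 0,
                                  low_shift = -2, high_shift = 2,
                                  transform = c("log2", "none"),
                                  seed = NULL) {
  transform <- match.arg(transform)
  if (!is_scalar_number(n_fibers) || n_fibers < 1 || n_fibers != round(n_fibers))
    stop("`n_fibers` must be a positive integer", call. = FALSE)
  check_positive_scalar(mass_sd, "mass_sd")
  if (!is_scalar_number(resid_sd) || resid_sd < 0)
    stop("`resid_sd` must be a single non-negative number", call. = FALSE)
  check_fraction(frac_low, "frac_low")
  check_fraction(frac_high, "frac_high")
  if (frac_low + frac_high > 1)
    stop("`frac_low` + `frac_high` must not exceed 1", call. = FALSE)
  if (!is_scalar_number(low_shift) || low_shift > 0)
    stop("`low_shift` must be <= 0 (deficient fibers sit below the control line)",
         call. = FALSE)
  if (!is_scalar_number(high_shift) || high_shift < 0)
    stop("`high_shift` must be >= 0 (overabundant fibers sit above the control line)",
         call. = FALSE)
  structure(
    list(n_fibers = as.integer(n_fibers),
         mass_mean = mass_mean, mass_sd = mass_sd,
         slope = slope, intercept = intercept, resid_sd = resid_sd,
         frac_low = frac_low, frac_high = frac_high,
         low_shift = low_shift, high_shift = high_shift,
         transform = transform, seed = seed),
    class = "fiber_population_spec")
}

#' @export
print.fiber_population_spec <- function(x, ...) {
  cat("Synthetic fiber population spec\n")
  cat(sprintf("  n_fibers: %d   transform: %s\n", x$n_fibers, x$transform))
  cat(sprintf("  mass ~ N(%.3g, %.3g); subunit = %.3g + %.3g * mass + N(0, %.3g)\n",
              x$mass_mean, x$mass_sd, x$intercept, x$slope, x$resid_sd))
  cat(sprintf("  classes: low %.1f%% (shift %+.3g), high %.1f%% (shift %+.3g)\n",
              100 * x$frac_low, x$low_shift, 100 * x$frac_high, x$high_shift))
  invisible(x)
}

#' Generate a synthetic per-fiber QIF table
#'
#' Draws one section of per-fiber intensities from a
#' [fiber_population_spec()]. Exactly `round(frac_low * n_fibers)` fibers
#' receive `low_shift` and `round(frac_high * n_fibers)` receive
#' `high_shift` on both subunit channels; which fibers, and all intensity
#' noise, are determined by the spec's seed. The generating class is kept in
#' `true_class` so recovery by the prediction-interval classifier can be
#' tested against ground truth.
#'
#' @param spec A [fiber_population_spec()].
#' @param section_id,participant,timepoint Labels copied onto every row;
#'   `timepoint` is one of `"unaffected"`, `"pre"`, `"post"`.
#' @param area_meanlog,area_sdlog Log-normal parameters for fiber
#'   cross-sectional area in square micrometres.
#'
#' @return A data frame with columns `fiber_id`, `section_id`, `participant`,
#'   `timepoint`, `vdac1`, `ndufb8`, `mtco1`, `area`, `true_class`.
#'   Intensities are on the raw (back-transformed) scale and strictly
#'   positive under the log2 transform.
#' @examples
#' spec <- fiber_population_spec(200, frac_low = 0.1, low_shift = -2, seed = 1)
#' fib <- generate_fiber_population(spec)
#' table(fib$true_class)
#' @export
generate_fiber_population <- function(spec,
                                      section_id = "S1",
                                      participant = "P1",
                                      timepoint = c("pre", "post", "unaffected"),
                                      area_meanlog = log(4000),
                                      area_sdlog = 0.3) {
  stopifnot(inherits(spec, "fiber_population_spec"))
  timepoint <- match.arg(timepoint)
  n <- spec$n_fibers
  n_low <- round(spec$frac_low * n)
  n_high <- round(spec$frac_high * n)

  with_seed(spec$seed, {
    cls <- sample(rep.int(c("low", "high", "normal"),
                          c(n_low, n_high, n - n_low - n_high)))
    mass_t <- stats::rnorm(n, spec$mass_mean, spec$mass_sd)
    shift <- ifelse(cls == "low", spec$low_shift,
                    ifelse(cls == "high", spec$high_shift, 0))
    mu <- spec$intercept + spec$slope * mass_t + shift
    ndufb8_t <- mu + stats::rnorm(n, 0, spec$resid_sd)
    mtco1_t <- mu + stats::rnorm(n, 0, spec$resid_sd)
    area <- stats::rlnorm(n, area_meanlog, area_sdlog)

    back <- if (spec$transform == "log2") function(z) 2^z else identity
    data.frame(
      fiber_id = sprintf("%s_f%04d", section_id, seq_len(n)),
      section_id = section_id,
      participant = participant,
      timepoint = timepoint,
      vdac1 = back(mass_t),
      ndufb8 = back(ndufb8_t),
      mtco1 = back(mtco1_t),
      area = area,
      true_class = factor(cls, levels = c("low", "normal", "high")),
      stringsAsFactors = FALSE)
  })
}

#' Generate synthetic immunoblot lane tables
#'
#' Emulates quantified optical densities (ODs) for the five OXPHOS antibody
#' cocktail subunits plus a stain-free total-protein lane signal, for the
#' three study groups. Group effects multiply a common subunit baseline;
#' lane-to-lane loading differences multiply both ODs and the total-protein
#' signal, so lane normalization removes them by construction.
#'
#' @param n_per_group Lanes per group.
#' @param group_effects Named list of per-group multiplicative effects on the
#'   subunit baseline (scalar or one value per subunit). Names must cover
#'   `"unaffected"`, `"dm1_pre"`, `"dm1_post"`.
#' @param baseline Named baseline OD-per-total-protein for the five subunits.
#' @param loading_cv,od_cv Log-normal coefficients of variation for lane
#'   loading and per-band measurement noise.
#' @param seed Integer seed or `NULL`.
#'
#' @return Data frame with columns `participant`, `timepoint`, `group`,
#'   `ndufb8`, `sdhb`, `uqcrc2`, `mtco1`, `atp5a`, `total_protein`.
#' @export
generate_blot_lanes <- function(n_per_group = 9,
                                group_effects = list(unaffected = 1,
                                                     dm1_pre = 1,
                                                     dm1_post = 1.3),
                                baseline = c(ndufb8 = 1, sdhb = 1.2,
                                             uqcrc2 = 1.5, mtco1 = 1.1,
                                             atp5a = 2),
                                loading_cv = 0.1, od_cv = 0.1,
                                seed = NULL) {
  stopifnot(all(c("unaffected", "dm1_pre", "dm1_post") %in% names(group_effects)))
  subunits <- names(baseline)
  with_seed(seed, {
    rows <- lapply(names(group_effects), function(g) {
      eff <- rep_len(unlist(group_effects[[g]]), length(subunits))
      loading <- stats::rlnorm(n_per_group, 0, loading_cv)
      od <- sapply(seq_along(subunits), function(j) {
        baseline[j] * eff[j] * loading *
          stats::rlnorm(n_per_group, 0, od_cv)
      })
      colnames(od) <- subunits
      is_dm1 <- g != "unaffected"
      data.frame(
        participant = if (is_dm1) sprintf("P%d", seq_len(n_per_group))
                      else sprintf("U%d", seq_len(n_per_group)),
        timepoint = switch(g, unaffected = "unaffected",
                           dm1_pre = "pre", dm1_post = "post"),
        group = if (is_dm1) "DM1" else "unaffected",
        od,
        total_protein = loading,
        stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
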