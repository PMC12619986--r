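#' Baseline cohort characteristics table
#'
#' Per-participant baseline characteristics of the study cohort: nine women
#' with DM1 (juvenile, adult or late-onset phenotype, with CTG repeat
#' counts) and nine age-matched unaffected women. Values are the published
#' per-participant entries; two unaffected NCAM+ percentages are missing
#' ("no data") and are kept as `NA`, excluded from all summaries.
#'
#' @return Data frame with one row per participant and columns
#'   `participant`, `group` (`"unaffected"` or `"DM1"`), `phenotype`
#'   (DM1 only), `age_years`, `weight_kg`, `height_cm`, `bmi_kg_m2`,
#'   `ctg_repeats` (DM1 only), `ncam_pos_pct` (% NCAM-positive fibers, may
#'   be `NA`).
#' @examples
#' coh <- cohort_fixture()
#' cohort_summarize(coh[coh$group == "DM1", ], "ctg_repeats")
#' @export
cohort_fixture <- function() {
  path <- system.file("extdata", "cohort_baseline.csv", package = "myoxphos",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(participant = "character",
                                 group = "character",
                                 phenotype = "character"))
}
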