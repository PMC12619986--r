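#' Subunit channels of the OXPHOS antibody cocktail
#'
#' Column names used by the densitometry functions: representative subunits
#' of Complex I (NDUFB8), Complex II (SDHB), Complex III (UQCRC2),
#' Complex IV (MT-CO1) and ATP synthase (ATP5A).
#' @return Character vector of the five subunit column names.
#' @export
oxphos_subunits <- function() c("ndufb8", "sdhb", "uqcrc2", "mtco1", "atp5a")

#' Normalize blot lane optical densities to total protein
#'
#' Divides every subunit optical density by the lane's stain-free
#' total-protein signal (the loading control), removing lane-to-lane
#' loading differences.
#'
#' @param lanes Data frame with the five subunit columns (see
#'   [oxphos_subunits()]) and a positive `total_protein` column.
#' @return The lane table with subunit columns replaced by their normalized
#'   values.
#' @export
lane_normalize <- function(lanes) {
  subunits <- intersect(oxphos_subunits(), names(lanes))
  if (!length(subunits))
    stop("`lanes` contains no OXPHOS subunit columns", call. = FALSE)
  check_columns(lanes, "total_protein", "`lanes`")
  if (any(!is.finite(lanes$total_protein) | lanes$total_protein <= 0))
    stop("`total_protein` must be positive in every lane", call. = FALSE)
  if (any(lanes[subunits] < 0, na.rm = TRUE))
    stop("optical densities must be non-negative", call. = FALSE)
  lanes[subunits] <- lanes[subunits] / lanes$total_protein
  lanes
}

#' Express normalized blot values relative to the unaffected group
#'
#' Divides each participant's normalized subunit value by the
#' unaffected-group mean of that subunit, so the unaffected group has mean
#' fold change exactly 1 per subunit by construction.
#'
#' @param lanes Normalized lane table (see [lane_normalize()]) with a
#'   `group` column containing at least one `"unaffected"` lane.
#' @param reference Group label to normalize against, default
#'   `"unaffected"`.
#' @return The lane table with subunit columns on the fold-change scale.
#' @export
fold_change_vs_unaffected <- function(lanes, reference = "unaffected") {
  subunits <- intersect(oxphos_subunits(), names(lanes))
  if (!length(subunits))
    stop("`lanes` contains no OXPHOS subunit columns", call. = FALSE)
  check_columns(lanes, "group", "`lanes`")
  ref <- lanes$group == reference
  if (!any(ref))
    stop("no lanes in reference group `", reference, "`", call. = FALSE)
  for (s in subunits) {
    ref_mean <- mean(lanes[[s]][ref], na.rm = TRUE)
    if (!is.finite(ref_mean) || ref_mean <= 0)
      stop("reference mean for `", s, "` is not positive", call. = FALSE)
    lanes[[s]] <- lanes[[s]] / ref_mean
  }
  lanes
}

#' OXPHOS protein content index
#'
#' Per-lane sum of the five representative OXPHOS subunit values, computed
#' on the fold-change scale (each subunit relative to the unaffected-group
#' mean) by default; a lane with any missing subunit gets `NA` with a
#' warning rather than an imputed value.
#'
#' @param lanes Lane table carrying the five subunit columns, typically the
#'   output of [lane_normalize()] then [fold_change_vs_unaffected()].
#' @return Numeric vector, one index per lane.
#' @examples
#' lanes <- generate_blot_lanes(seed = 1)
#' fc <- fold_change_vs_unaffected(lane_normalize(lanes))
#' tapply(oxphos_index(fc), fc$timepoint, mean)
#' @export
oxphos_index <- function(lanes) {
  subunits <- oxphos_subunits()
  check_columns(lanes, subunits, "`lanes`")
  vals <- as.matrix(lanes[subunits])
  idx <- rowSums(vals)
  if (anyNA(idx))
    warning(sum(is.na(idx)), " lane(s) with missing subunit values excluded from the index")
  unname(idx)
}
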