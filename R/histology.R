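#' Percentage of marker-positive fibers in a sample
#'
#' Computes `100 * positives / total` for one histological marker in one
#' sample's per-fiber table. Samples with fewer than `min_fibers` evaluable
#' fibers are flagged `low_n` (attribute) but not dropped, mirroring the
#' counting convention that at least 100 myofibers should be analyzed per
#' sample.
#'
#' @param table Per-fiber data frame (see [generate_histology_table()]).
#' @param marker Column name of a logical flag: one of `"ncam_pos"`,
#'   `"central_nucleus"`, `"nuclear_clump"`, `"damaged_laminin"`.
#' @param min_fibers Minimum fiber count before the `low_n` flag, default 100.
#' @return Percentage in `[0, 100]` with attributes `n_fibers` and `low_n`.
#' @examples
#' h <- generate_histology_table(500, seed = 1)
#' marker_proportion(h, "central_nucleus")
#' @export
marker_proportion <- function(table, marker, min_fibers = 100) {
  if (!nrow(table)) stop("empty fiber table", call. = FALSE)
  check_columns(table, marker, "`table`")
  flags <- table[[marker]]
  flags <- flags[!is.na(flags)]
  if (!length(flags)) stop("no evaluable fibers for `", marker, "`", call. = FALSE)
  structure(100 * sum(flags) / length(flags),
            n_fibers = length(flags),
            low_n = length(flags) < min_fibers)
}

#' Per-sample summary of all integrity markers
#'
#' Applies [marker_proportion()] to every marker for every
#' participant-by-timepoint sample in a pooled per-fiber table.
#'
#' @param table Per-fiber data frame with `participant` and `timepoint`
#'   columns and the four marker flags.
#' @param markers Marker columns to summarize.
#' @param min_fibers Low-count flag threshold per sample.
#' @return Data frame with one row per sample: marker percentages,
#'   `n_fibers`, and `low_n`.
#' @export
marker_summary <- function(table,
                           markers = c("ncam_pos", "central_nucleus",
                                       "nuclear_clump", "damaged_laminin"),
                           min_fibers = 100) {
  check_columns(table, c("participant", "timepoint", markers), "`table`")
  key <- interaction(table$participant, table$timepoint, drop = TRUE)
  rows <- lapply(split(table, key), function(d) {
    pcts <- vapply(markers, function(m)
      as.numeric(marker_proportion(d, m, min_fibers)), numeric(1))
    cbind(data.frame(participant = d$participant[1],
                     timepoint = d$timepoint[1], stringsAsFactors = FALSE),
          as.data.frame(as.list(pcts)),
          data.frame(n_fibers = nrow(d), low_n = nrow(d) < min_fibers))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cross-sectional area contrast of NCAM+ vs NCAM- fibers
#'
#' Percent difference in mean fiber cross-sectional area between NCAM+
#' (denervated) and NCAM- fibers: `100 * (mean(pos) - mean(neg)) /
#' mean(neg)`. A negative value means NCAM+ fibers are smaller, the
#' signature of genuine denervation atrophy.
#'
#' @param pos_csa,neg_csa Numeric CSA values (square micrometres) of NCAM+
#'   and NCAM- fibers; both non-empty.
#' @return Percent difference (scalar).
#' @export
csa_contrast <- function(pos_csa, neg_csa) {
  pos_csa <- pos_csa[is.finite(pos_csa)]
  neg_csa <- neg_csa[is.finite(neg_csa)]
  if (!length(pos_csa) || !length(neg_csa))
    stop("both CSA groups must be non-empty", call. = FALSE)
  100 * (mean(pos_csa) - mean(neg_csa)) / mean(neg_csa)
}

#' Paired participant-level NCAM CSA analysis
#'
#' For each participant, pools fibers and computes mean CSA of NCAM+ and
#' NCAM- fibers; participants lacking either group are dropped. Returns the
#' per-participant contrasts and the Wilcoxon matched-pairs signed-rank
#' test across participants.
#'
#' @param table Per-fiber data frame with `participant`, `ncam_pos`, `csa`.
#' @return List with `per_participant` (data frame of paired means and
#'   contrast), `mean_contrast_pct`, and `wilcoxon` (the paired test, or
#'   `NULL` when fewer than 2 complete participants).
#' @export
ncam_csa_analysis <- function(table) {
  check_columns(table, c("participant", "ncam_pos", "csa"), "`table`")
  rows <- lapply(split(table, table$participant), function(d) {
    pos <- d$csa[d$ncam_pos %in% TRUE]
    neg <- d$csa[d$ncam_pos %in% FALSE]
    if (!length(pos) || !length(neg)) return(NULL)
    data.frame(participant = d$participant[1],
               mean_csa_pos = mean(pos), mean_csa_neg = mean(neg),
               contrast_pct = csa_contrast(pos, neg),
               stringsAsFactors = FALSE)
  })
  pp <- do.call(rbind, rows)
  if (is.null(pp) || !nrow(pp))
    stop("no participant has both NCAM+ and NCAM- fibers", call. = FALSE)
  rownames(pp) <- NULL
  wt <- if (nrow(pp) >= 2)
    compare_paired(pp$mean_csa_pos, pp$mean_csa_neg) else NULL
  list(per_participant = pp,
       mean_contrast_pct = mean(pp$contrast_pct),
       wilcoxon = wt)
}
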