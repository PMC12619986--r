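#' Mean and SD of a cohort column with explicit missing handling
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) over
#' the non-missing values of one column, reporting how many values were
#' used. A single non-missing value yields an `NA` SD with a `single_value`
#' flag rather than an error.
#'
#' @param table Cohort data frame (e.g. [cohort_fixture()]).
#' @param column Column name to summarize.
#' @return List with `mean`, `sd`, `n_used`, `single_value`.
#' @examples
#' coh <- cohort_fixture()
#' cohort_summarize(coh[coh$group == "DM1", ], "ctg_repeats")
#' @export
cohort_summarize <- function(table, column) {
  check_columns(table, column, "`table`")
  v <- table[[column]]
  v <- v[!is.na(v)]
  if (!length(v)) stop("all values of `", column, "` are missing", call. = FALSE)
  list(mean = mean(v),
       sd = if (length(v) > 1) stats::sd(v) else NA_real_,
       n_used = length(v),
       single_value = length(v) == 1)
}

#' Mann-Whitney comparison of two independent groups
#'
#' Two-sided rank-sum test between independent samples (e.g. unaffected vs
#' DM1-PRE), exact when both samples are small and untied, with the normal
#' approximation and tie correction otherwise (the base-R switching rule).
#' Results with `0.05 <= p < 0.1` are labelled `"trend"` per the study
#' reporting convention.
#'
#' @param x,y Numeric vectors, both non-empty; `NA` dropped.
#' @param trend_band Upper p bound for the trend label, default 0.1.
#' @return List with `statistic` (U), `p_value`, `label`
#'   (`"significant"`, `"trend"` or `"ns"`).
#' @export
compare_independent <- function(x, y, trend_band = 0.1) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y))
    stop("both groups must contain non-missing values", call. = FALSE)
  wt <- suppressWarnings(stats::wilcox.test(x, y))
  list(statistic = unname(wt$statistic),
       p_value = wt$p.value,
       label = .p_label(wt$p.value, trend_band))
}

#' Wilcoxon matched-pairs signed-rank comparison
#'
#' Two-sided paired signed-rank test (e.g. DM1-PRE vs DM1-POST), exact for
#' small untied samples. All-zero differences yield `p = 1` by convention
#' (no evidence of change).
#'
#' @param pre,post Equal-length numeric vectors; pairs with any `NA` are
#'   dropped listwise.
#' @param trend_band Upper p bound for the trend label, default 0.1.
#' @return List with `statistic` (V), `p_value`, `label`, `n_pairs`.
#' @export
compare_paired <- function(pre, post, trend_band = 0.1) {
  if (length(pre) != length(post))
    stop("`pre` and `post` must have the same length", call. = FALSE)
  ok <- !is.na(pre) & !is.na(post)
  pre <- pre[ok]; post <- post[ok]
  if (!length(pre)) stop("no complete pairs", call. = FALSE)
  d <- post - pre
  if (all(d == 0))
    return(list(statistic = NA_real_, p_value = 1,
                label = "ns", n_pairs = length(d)))
  wt <- suppressWarnings(stats::wilcox.test(post, pre, paired = TRUE))
  list(statistic = unname(wt$statistic),
       p_value = wt$p.value,
       label = .p_label(wt$p.value, trend_band),
       n_pairs = length(d))
}

.p_label <- function(p, trend_band = 0.1) {
  if (p < 0.05) "significant" else if (p < trend_band) "trend" else "ns"
}

#' Sidak adjustment for k comparisons
#'
#' `p_adj = 1 - (1 - p)^k`; satisfies `p <= p_adj <= min(1, k * p)`.
#'
#' @param p Numeric p-values in `[0, 1]`.
#' @param k Number of comparisons in the family (>= 1).
#' @return Adjusted p-values.
#' @export
sidak_adjust <- function(p, k) {
  if (!is_scalar_number(k) || k < 1)
    stop("`k` must be >= 1", call. = FALSE)
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop("`p` must be in [0, 1]", call. = FALSE)
  1 - (1 - p)^k
}

#' Two-way ANOVA with Sidak-adjusted pairwise group comparisons
#'
#' Fits the group-by-state two-way ANOVA used for per-state bioenergetics
#' panels (e.g. respiration rate by group across titration states) and
#' Sidak-adjusts the per-state pairwise group t-tests. With
#' `repeated = TRUE` (both factors within subject, e.g. DM1-PRE vs
#' DM1-POST across states) the subject stratum is included via an error
#' term, which requires a complete balanced design.
#'
#' @param data Long-format data frame.
#' @param value,group,state Column names of the response, the group factor
#'   and the state factor.
#' @param subject Column name identifying subjects (required when
#'   `repeated = TRUE`).
#' @param repeated Logical: repeated-measures design with both factors
#'   within subject.
#' @return List with `anova` (the [stats::aov()] summary), `pairwise`
#'   (per-state group contrast t-tests with Sidak-adjusted p), `k` (number
#'   of comparisons adjusted for).
#' @export
two_way_anova_sidak <- function(data, value, group, state,
                                subject = NULL, repeated = FALSE) {
  check_columns(data, c(value, group, state), "`data`")
  d <- data.frame(value = data[[value]],
                  group = factor(data[[group]]),
                  state = factor(data[[state]]))
  if (repeated) {
    if (is.null(subject))
      stop("`subject` is required for a repeated-measures design", call. = FALSE)
    check_columns(data, subject, "`data`")
    d$subject <- factor(data[[subject]])
    counts <- table(d$subject, d$group, d$state)
    if (any(counts != 1))
      stop("repeated-measures design must be complete: one value per subject x group x state cell",
           call. = FALSE)
    fit <- stats::aov(value ~ group * state + Error(subject / (group * state)),
                      data = d)
  } else {
    fit <- stats::aov(value ~ group * state, data = d)
  }

  # Sidak-adjusted pairwise group comparisons within each state
  groups <- levels(d$group)
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  states <- levels(d$state)
  k <- length(pairs) * length(states)
  rows <- lapply(states, function(s) {
    do.call(rbind, lapply(pairs, function(pr) {
      a <- d$value[d$state == s & d$group == pr[1]]
      b <- d$value[d$state == s & d$group == pr[2]]
      tt <- stats::t.test(a, b, paired = repeated)
      data.frame(state = s, group1 = pr[1], group2 = pr[2],
                 p_raw = tt$p.value,
                 p_sidak = sidak_adjust(tt$p.value, k),
                 stringsAsFactors = FALSE)
    }))
  })
  list(anova = summary(fit), pairwise = do.call(rbind, rows), k = k)
}
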