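# Uncertainty and significance for post-minus-pre changes in fiber class
# proportions. The resampling unit is the fiber: classes are fixed by the
# shared control model, so resampling reduces to exact draws on the class
# counts (multinomial for the within-timepoint bootstrap, hypergeometric for
# the pooled re-split permutation null), which is distributionally identical
# to resampling fiber labels and fully vectorized.

.class_counts <- function(classes) {
  classes <- stats::na.omit(classes)
  if (!length(classes)) stop("no classified fibers", call. = FALSE)
  table(factor(classes, levels = c("low", "normal", "high")))
}

#' Bootstrap confidence intervals for delta fiber proportions
#'
#' Resamples fibers with replacement independently within the pre and post
#' sets (B replicates), recomputes the post-minus-pre change in the
#' proportion of `high` and `low` fibers each time, and returns percentile
#' confidence intervals. Deterministic under a fixed seed and B.
#'
#' @param pre,post Class factors from [classify_fibers()] (levels `low`,
#'   `normal`, `high`; `NA` dropped) for the participant's fibers at each
#'   timepoint, classified under one shared control model.
#' @param B Number of bootstrap replicates (>= 100).
#' @param seed Integer seed or `NULL`.
#' @param level Confidence level for the percentile interval, default 0.95.
#' @return List with `delta_high`, `delta_low` (point estimates),
#'   `ci_high`, `ci_low` (percentile intervals), `B`, `level`.
#' @export
bootstrap_delta <- function(pre, post, B = 1000, seed = NULL, level = 0.95) {
  if (!is_scalar_number(B) || B < 100)
    stop("`B` must be at least 100", call. = FALSE)
  cp <- .class_counts(pre); cq <- .class_counts(post)
  n_pre <- sum(cp); n_post <- sum(cq)
  probs <- c(1 - level, 1 + level) / 2

  with_seed(seed, {
    bp <- stats::rmultinom(B, n_pre, cp / n_pre)
    bq <- stats::rmultinom(B, n_post, cq / n_post)
    d_high <- bq["high", ] / n_post - bp["high", ] / n_pre
    d_low <- bq["low", ] / n_post - bp["low", ] / n_pre
    list(delta_high = unname(cq[["high"]] / n_post - cp[["high"]] / n_pre),
         delta_low = unname(cq[["low"]] / n_post - cp[["low"]] / n_pre),
         ci_high = unname(stats::quantile(d_high, probs)),
         ci_low = unname(stats::quantile(d_low, probs)),
         B = as.integer(B), level = level)
  })
}

#' Permutation test for delta fiber proportions
#'
#' Builds the null distribution of the post-minus-pre change in class
#' proportion by pooling the participant's pre and post fibers and randomly
#' re-splitting them into groups of the original sizes. For a single class
#' the count landing in the post group under a re-split is hypergeometric,
#' so the null is drawn exactly and vectorized from that law; two-sided
#' p-values use the add-one rule `p = (1 + #{|d*| >= |d|}) / (n_perm + 1)`,
#' so p is never 0 and a degenerate pool (all fibers one class) gives p = 1.
#' Tie comparisons are carried out on integer-scaled deltas, so they are
#' exact. This pooled re-split null is a stand-in for the original study
#' software's unpublished resampling scheme and is labelled as such in the
#' output (`null` field).
#'
#' @inheritParams bootstrap_delta
#' @param n_perm Number of permutations (>= 99).
#' @return List with `delta_high`, `delta_low`, `p_high`, `p_low`,
#'   `n_perm`, and `null = "pooled_resplit"`.
#' @export
permutation_test_delta <- function(pre, post, n_perm = 999, seed = NULL) {
  if (!is_scalar_number(n_perm) || n_perm < 99)
    stop("`n_perm` must be at least 99", call. = FALSE)
  cp <- .class_counts(pre); cq <- .class_counts(post)
  n_pre <- sum(cp); n_post <- sum(cq)
  N <- n_pre + n_post

  one_class <- function(cls) {
    tot <- cp[[cls]] + cq[[cls]]
    # integer-scaled delta: delta * n_pre * n_post
    d_obs <- as.numeric(cq[[cls]]) * n_pre - as.numeric(cp[[cls]]) * n_post
    c_post <- stats::rhyper(n_perm, m = tot, n = N - tot, k = n_post)
    d_null <- as.numeric(c_post) * n_pre - as.numeric(tot - c_post) * n_post
    list(delta = d_obs / (as.numeric(n_pre) * n_post),
         p = (1 + sum(abs(d_null) >= abs(d_obs))) / (n_perm + 1))
  }
  with_seed(seed, {
    high <- one_class("high")
    low <- one_class("low")
    list(delta_high = high$delta, delta_low = low$delta,
         p_high = high$p, p_low = low$p,
         n_perm = as.integer(n_perm), null = "pooled_resplit")
  })
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up FDR adjustment across the family of all tests of one run
#' (participants x channels x directions). Thin wrapper over
#' [stats::p.adjust()] with input validation: adjusted values are monotone
#' (never below the raw p) and order-preserving.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Vector of q-values, same length and order as `p`.
#' @export
fdr_adjust <- function(p) {
  if (!length(p) || !is.numeric(p) || anyNA(p) || any(p <= 0 | p > 1))
    stop("`p` must be p-values in (0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Direction-plus-significance call for a delta fiber proportion
#'
#' Applies the study call rule: a change in the `high` class is a
#' significant increase iff `delta > 0` and `p < alpha`; a change in the
#' `low` class is a significant decrease iff `delta < 0` and `p < alpha`.
#' A significant change in the opposite direction (fewer overabundant or
#' more deficient fibers after intervention) is reported as
#' `"significant_negative_change"`; anything non-significant is `"ns"`.
#'
#' @param delta Post-minus-pre change in the class proportion.
#' @param p Significance value to threshold (permutation p or FDR q).
#' @param class `"high"` or `"low"` — which class proportion `delta` refers to.
#' @param alpha Significance threshold, default 0.05.
#' @return Character vector of calls (vectorized over `delta` and `p`).
#' @export
call_significance <- function(delta, p, class = c("high", "low"),
                              alpha = 0.05) {
  class <- match.arg(class)
  stopifnot(length(delta) == length(p))
  sig <- p < alpha
  good <- if (class == "high") delta > 0 else delta < 0
  bad <- if (class == "high") delta < 0 else delta > 0
  out <- rep("ns", length(delta))
  out[sig & good] <- if (class == "high") "significant_increase_high"
                     else "significant_decrease_low"
  out[sig & bad] <- "significant_negative_change"
  out
}

#' Full uncertainty analysis for one participant and channel
#'
#' Convenience orchestration of [bootstrap_delta()],
#' [permutation_test_delta()] and [call_significance()] for one
#' participant's pre/post fiber classes under a shared model.
#'
#' @inheritParams bootstrap_delta
#' @inheritParams permutation_test_delta
#' @param alpha Significance threshold for the direction calls.
#' @return One-row data frame (class `"delta_result"`) with the deltas,
#'   bootstrap CI bounds, permutation p-values and calls. Combine rows
#'   across participants/channels, then apply [fdr_adjust()] to the pooled
#'   p-values for the FDR family of the run.
#' @examples
#' spec_pre <- fiber_population_spec(300, frac_high = 0.05, seed = 1)
#' spec_post <- fiber_population_spec(300, frac_high = 0.25, seed = 2)
#' ctrl <- generate_fiber_population(fiber_population_spec(1000, seed = 3),
#'                                   timepoint = "unaffected")
#' m <- fit_pi_model(ctrl, "ndufb8")
#' delta_test(classify_fibers(m, generate_fiber_population(spec_pre)),
#'            classify_fibers(m, generate_fiber_population(spec_post)),
#'            seed = 4)
#' @export
delta_test <- function(pre, post, B = 1000, n_perm = 999, seed = NULL,
                       level = 0.95, alpha = 0.05) {
  boot <- bootstrap_delta(pre, post, B = B, level = level,
                          seed = if (is.null(seed)) NULL
                                 else substream_seed(seed, "boot"))
  perm <- permutation_test_delta(pre, post, n_perm = n_perm,
                                 seed = if (is.null(seed)) NULL
                                        else substream_seed(seed, "perm"))
  out <- data.frame(
    delta_high = boot$delta_high, delta_low = boot$delta_low,
    ci_high_lo = boot$ci_high[1], ci_high_up = boot$ci_high[2],
    ci_low_lo = boot$ci_low[1], ci_low_up = boot$ci_low[2],
    p_perm_high = perm$p_high, p_perm_low = perm$p_low,
    call_high = call_significance(boot$delta_high, perm$p_high, "high", alpha),
    call_low = call_significance(boot$delta_low, perm$p_low, "low", alpha),
    B = boot$B, n_perm = perm$n_perm,
    stringsAsFactors = FALSE)
  class(out) <- c("delta_result", "data.frame")
  out
}

#' Bonferroni-adjusted t-tests on participant mean values
#'
#' Bilateral (two-sided) t-test comparing two sets of per-participant mean
#' values, with Bonferroni adjustment for a family of `k` comparisons:
#' `p_adj = min(1, k * p)`.
#'
#' @param x,y Numeric vectors of mean values for the two groups.
#' @param k Number of comparisons in the family (>= 1).
#' @param paired Passed to [stats::t.test()].
#' @return List with `statistic`, `p_value`, `p_adjusted`, `k`.
#' @export
bonferroni_mean_tests <- function(x, y, k = 1, paired = FALSE) {
  if (!is_scalar_number(k) || k < 1)
    stop("`k` must be >= 1", call. = FALSE)
  tt <- stats::t.test(x, y, paired = paired)
  list(statistic = unname(tt$statistic),
       p_value = tt$p.value,
       p_adjusted = min(1, k * tt$p.value),
       k = k)
}
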