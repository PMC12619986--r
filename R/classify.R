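#' Classify fibers against a control prediction interval
#'
#' Labels each fiber `"low"` (below the lower prediction bound: deficient
#' for the modelled complex), `"normal"` (inside the band or exactly on a
#' bound — boundary ties are resolved conservatively to normal) or `"high"`
#' (above the upper bound: overabundant). Fibers whose intensities cannot be
#' transformed (non-positive under log2, or non-finite) are excluded with
#' `NA` and counted in the `n_flagged` attribute rather than imputed.
#'
#' @param model A [fit_pi_model()] fit.
#' @param fibers Data frame with the model's mass-marker and channel columns.
#' @return Factor of levels `low`, `normal`, `high` aligned with the rows of
#'   `fibers` (`NA` for excluded fibers), with attributes `n_flagged` and
#'   `model_id`.
#' @examples
#' ctrl <- generate_fiber_population(
#'   fiber_population_spec(500, seed = 1), timepoint = "unaffected")
#' m <- fit_pi_model(ctrl, "ndufb8")
#' test <- generate_fiber_population(
#'   fiber_population_spec(100, frac_low = 0.2, low_shift = -3, seed = 2))
#' table(classify_fibers(m, test), test$true_class)
#' @export
classify_fibers <- function(model, fibers) {
  stopifnot(inherits(model, "pi_model"))
  check_columns(fibers, c(model$mass, model$channel), "`fibers`")
  xr <- fibers[[model$mass]]
  yr <- fibers[[model$channel]]
  ok <- is.finite(xr) & is.finite(yr)
  if (model$transform == "log2") ok <- ok & xr > 0 & yr > 0

  cls <- rep(NA_character_, length(xr))
  if (any(ok)) {
    pr <- predict(model, xr[ok], interval = "prediction")
    y <- .pi_tf(model, yr[ok])
    cls[ok] <- ifelse(y < pr$lwr, "low", ifelse(y > pr$upr, "high", "normal"))
  }
  structure(factor(cls, levels = c("low", "normal", "high")),
            n_flagged = sum(!ok),
            model_id = pi_model_id(model))
}

# stable fingerprint of a fitted model so deltas can refuse mixed models
pi_model_id <- function(model) {
  paste(model$channel, model$transform,
        format(model$slope, digits = 12), format(model$intercept, digits = 12),
        format(model$resid_sd, digits = 12), model$n_control, sep = "|")
}

#' Empirical class proportions of a classified fiber set
#'
#' @param classes Factor from [classify_fibers()] (or any factor with levels
#'   `low`, `normal`, `high`); `NA` entries (QC-excluded fibers) are dropped.
#' @return Object of class `"class_proportions"`: list with `p_low`,
#'   `p_normal`, `p_high` (summing to 1), `n_fibers`, and the originating
#'   `model_id` when available.
#' @export
class_proportions <- function(classes) {
  classes <- stats::na.omit(classes)
  n <- length(classes)
  if (n == 0) stop("no classified fibers", call. = FALSE)
  counts <- table(factor(classes, levels = c("low", "normal", "high")))
  structure(list(p_low = unname(counts[["low"]]) / n,
                 p_normal = unname(counts[["normal"]]) / n,
                 p_high = unname(counts[["high"]]) / n,
                 n_fibers = n,
                 model_id = attr(classes, "model_id", exact = TRUE)),
            class = "class_proportions")
}

#' @export
print.class_proportions <- function(x, ...) {
  cat(sprintf("Fiber class proportions (n = %d): low %.1f%%, normal %.1f%%, high %.1f%%\n",
              x$n_fibers, 100 * x$p_low, 100 * x$p_normal, 100 * x$p_high))
  invisible(x)
}

#' Post-minus-pre change in fiber class proportions
#'
#' Computes the intervention deltas for one participant and channel:
#' `delta_high` (change in the proportion of overabundant fibers) and
#' `delta_low` (change in the proportion of deficient fibers), both in
#' `[-1, 1]`. Both proportion sets must come from classification under the
#' same fitted control model, so the delta is not confounded by refitting.
#'
#' @param pre,post [class_proportions()] of the same participant's fibers
#'   before and after intervention, classified with one shared model.
#' @return Object of class `"delta_proportions"`: list with `delta_high`,
#'   `delta_low`, `delta_normal`, and per-timepoint fiber counts.
#' @export
delta_proportions <- function(pre, post) {
  stopifnot(inherits(pre, "class_proportions"),
            inherits(post, "class_proportions"))
  if (!is.null(pre$model_id) && !is.null(post$model_id) &&
      !identical(pre$model_id, post$model_id))
    stop("pre and post proportions were classified under different models",
         call. = FALSE)
  structure(list(delta_high = post$p_high - pre$p_high,
                 delta_low = post$p_low - pre$p_low,
                 delta_normal = post$p_normal - pre$p_normal,
                 n_pre = pre$n_fibers, n_post = post$n_fibers),
            class = "delta_proportions")
}

#' @export
print.delta_proportions <- function(x, ...) {
  cat(sprintf("Delta fiber proportions (post - pre; n = %d/%d):\n",
              x$n_pre, x$n_post))
  cat(sprintf("  delta_high %+0.3f   delta_low %+0.3f   delta_normal %+0.3f\n",
              x$delta_high, x$delta_low, x$delta_normal))
  invisible(x)
}
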