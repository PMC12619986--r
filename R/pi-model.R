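#' Fit a control prediction-interval regression for one OXPHOS channel
#'
#' Fits, on a population of unaffected control fibers, the linear regression
#' of an OXPHOS subunit intensity (Complex I NDUFB8 or Complex IV MT-CO1) on
#' the mitochondrial mass marker VDAC1, and stores everything needed to form
#' the two-sided prediction interval for a new fiber:
#' \deqn{\hat y(x) \pm t_{1-\alpha/2,\,n-2}\; s
#'   \sqrt{1 + 1/n + (x - \bar x)^2 / S_{xx}}}
#' where `s` is the residual standard deviation and `Sxx` the centred sum of
#' squares of the control mass signal. Fibers from affected muscle falling
#' below the lower bound are called deficient ("low"), above the upper bound
#' overabundant ("high"); see [classify_fibers()].
#'
#' Intensities are log2-transformed before regression by default, so the
#' control relationship is a power law on the raw scale and classification
#' is invariant to a common positive rescaling of the raw intensities (up to
#' refitting the intercept on equally rescaled controls).
#'
#' @param control_fibers Data frame of unaffected fibers with positive
#'   intensity columns (at least the mass marker and the chosen channel).
#'   All unaffected fibers are pooled into one model per channel.
#' @param channel Subunit channel to model: `"ndufb8"` or `"mtco1"`.
#' @param transform `"log2"` (default) or `"none"`.
#' @param level Prediction-interval coverage level, default 0.95.
#' @param mass Name of the mass-marker column, default `"vdac1"`.
#'
#' @return An object of class `"pi_model"` with components `slope`,
#'   `intercept`, `resid_sd`, `n_control`, `x_mean`, `x_sumsq_centered`,
#'   `t_crit`, `level`, `channel`, `transform`, `mass`, and the transformed
#'   control points `x`, `y`.
#' @seealso [predict.pi_model()], [classify_fibers()], [simulate.pi_model()]
#' @examples
#' ctrl <- generate_fiber_population(
#'   fiber_population_spec(500, seed = 1), timepoint = "unaffected")
#' m <- fit_pi_model(ctrl, "ndufb8")
#' summary(m)
#' @export
fit_pi_model <- function(control_fibers,
                         channel = c("ndufb8", "mtco1"),
                         transform = c("log2", "none"),
                         level = 0.95,
                         mass = "vdac1") {
  channel <- match.arg(channel)
  transform <- match.arg(transform)
  check_columns(control_fibers, c(mass, channel), "`control_fibers`")
  if (!is_scalar_number(level) || level <= 0 || level >= 1)
    stop("`level` must be in (0, 1)", call. = FALSE)

  xr <- control_fibers[[mass]]
  yr <- control_fibers[[channel]]
  keep <- is.finite(xr) & is.finite(yr)
  if (transform == "log2") keep <- keep & xr > 0 & yr > 0
  n_dropped <- sum(!keep)
  xr <- xr[keep]; yr <- yr[keep]
  n <- length(xr)
  if (n < 3)
    stop("need at least 3 usable control fibers, got ", n, call. = FALSE)

  tf <- if (transform == "log2") log2 else identity
  x <- tf(xr); y <- tf(yr)
  x_mean <- mean(x)
  sxx <- sum((x - x_mean)^2)
  if (sxx <= 0)
    stop("control mass-marker signal has zero spread; cannot regress",
         call. = FALSE)
  slope <- sum((x - x_mean) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * x_mean
  resid <- y - (intercept + slope * x)
  resid_sd <- sqrt(sum(resid^2) / (n - 2))

  structure(
    list(slope = slope, intercept = intercept, resid_sd = resid_sd,
         n_control = n, x_mean = x_mean, x_sumsq_centered = sxx,
         t_crit = stats::qt(1 - (1 - level) / 2, df = n - 2),
         level = level, channel = channel, transform = transform,
         mass = mass, x = x, y = y, n_dropped = n_dropped,
         call = match.call()),
    class = "pi_model")
}

# transform raw intensities onto the model scale
.pi_tf <- function(object, v) if (object$transform == "log2") log2(v) else v

# prediction-interval halfwidth at transformed abscissa x
.pi_halfwidth <- function(object, x) {
  object$t_crit * object$resid_sd *
    sqrt(1 + 1 / object$n_control +
           (x - object$x_mean)^2 / object$x_sumsq_centered)
}

#' @export
print.pi_model <- function(x, ...) {
  cat(sprintf("Control prediction-interval model (%s ~ %s, %s scale)\n",
              toupper(x$channel), toupper(x$mass), x$transform))
  cat(sprintf("  fitted on %d control fibers%s\n", x$n_control,
              if (x$n_dropped) sprintf(" (%d dropped in QC)", x$n_dropped) else ""))
  cat(sprintf("  slope %.4f, intercept %.4f, residual SD %.4f\n",
              x$slope, x$intercept, x$resid_sd))
  cat(sprintf("  %.0f%% prediction band, t-critical %.3f (df = %d)\n",
              100 * x$level, x$t_crit, x$n_control - 2L))
  invisible(x)
}

#' @export
coef.pi_model <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
residuals.pi_model <- function(object, ...) {
  object$y - (object$intercept + object$slope * object$x)
}

#' Summarize a fitted control prediction-interval model
#'
#' @param object A [fit_pi_model()] fit.
#' @param ... Unused.
#' @return An object of class `"summary.pi_model"` carrying coefficient
#'   standard errors, R-squared, and the interval geometry.
#' @export
summary.pi_model <- function(object, ...) {
  se_slope <- object$resid_sd / sqrt(object$x_sumsq_centered)
  se_int <- object$resid_sd *
    sqrt(1 / object$n_control + object$x_mean^2 / object$x_sumsq_centered)
  r2 <- 1 - sum(residuals(object)^2) / sum((object$y - mean(object$y))^2)
  structure(list(model = object,
                 se = c(intercept = se_int, slope = se_slope),
                 r_squared = r2,
                 halfwidth_at_mean = .pi_halfwidth(object, object$x_mean)),
            class = "summary.pi_model")
}

#' @export
print.summary.pi_model <- function(x, ...) {
  m <- x$model
  print(m)
  cat(sprintf("  SE(slope) %.4g, SE(intercept) %.4g, R-squared %.3f\n",
              x$se[["slope"]], x$se[["intercept"]], x$r_squared))
  cat(sprintf("  interval halfwidth at mean mass signal: %.4f (%s units)\n",
              x$halfwidth_at_mean, m$transform))
  invisible(x)
}

#' Predict subunit signal and prediction bounds for new fibers
#'
#' @param object A [fit_pi_model()] fit.
#' @param newdata Data frame containing the mass-marker column, or a numeric
#'   vector of raw mass-marker intensities.
#' @param interval `"prediction"` (default) to include the lower/upper
#'   prediction bounds, `"none"` for the fitted line only.
#' @param ... Unused.
#' @return Data frame with `fit` and, for `interval = "prediction"`, `lwr`
#'   and `upr`, all on the model's transformed scale.
#' @export
predict.pi_model <- function(object, newdata,
                             interval = c("prediction", "none"), ...) {
  interval <- match.arg(interval)
  xr <- if (is.data.frame(newdata)) {
    check_columns(newdata, object$mass, "`newdata`")
    newdata[[object$mass]]
  } else as.numeric(newdata)
  x <- .pi_tf(object, xr)
  fit <- object$intercept + object$slope * x
  if (interval == "none") return(data.frame(fit = fit))
  hw <- .pi_halfwidth(object, x)
  data.frame(fit = fit, lwr = fit - hw, upr = fit + hw)
}

#' Simulate new control fibers from a fitted model
#'
#' Draws new fibers from the fitted control population: mass-marker values
#' are resampled with replacement from the stored control fibers (or taken
#' from `newmass`) and subunit signal is drawn about the fitted line with
#' the fitted residual SD. Useful for held-out coverage checks: a new fiber
#' drawn this way should fall inside the prediction interval with
#' probability close to the model's `level`.
#'
#' @param object A [fit_pi_model()] fit.
#' @param nsim Number of fibers to draw.
#' @param seed Integer seed or `NULL`.
#' @param newmass Optional raw-scale mass-marker intensities to condition on
#'   (recycled to `nsim`).
#' @param ... Unused.
#' @return Data frame with raw-scale columns named after the model's mass
#'   marker and channel.
#' @export
simulate.pi_model <- function(object, nsim = 1, seed = NULL,
                              newmass = NULL, ...) {
  with_seed(seed, {
    x <- if (is.null(newmass)) sample(object$x, nsim, replace = TRUE)
         else rep_len(.pi_tf(object, newmass), nsim)
    y <- object$intercept + object$slope * x +
      stats::rnorm(nsim, 0, object$resid_sd)
    back <- if (object$transform == "log2") function(z) 2^z else identity
    out <- data.frame(back(x), back(y))
    names(out) <- c(object$mass, object$channel)
    out
  })
}

#' @export
plot.pi_model <- function(x, n_grid = 200, ...) {
  grid <- seq(min(x$x), max(x$x), length.out = n_grid)
  hw <- .pi_halfwidth(x, grid)
  fit <- x$intercept + x$slope * grid
  graphics::plot(x$x, x$y, pch = 16, cex = 0.4, col = "grey50",
                 xlab = sprintf("%s (%s)", toupper(x$mass), x$transform),
                 ylab = sprintf("%s (%s)", toupper(x$channel), x$transform),
                 ...)
  graphics::lines(grid, fit, lwd = 2)
  graphics::lines(grid, fit - hw, lty = 2)
  graphics::lines(grid, fit + hw, lty = 2)
  invisible(x)
}
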