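# Shared fixtures, built once per test run.

# pooled unaffected control fibers and a fitted NDUFB8 model
ctrl_fibers <- generate_fiber_population(
  fiber_population_spec(2000, seed = 101), timepoint = "unaffected")
ctrl_model <- fit_pi_model(ctrl_fibers, "ndufb8")

# independent reference fit via lm() on the same transformed data
ctrl_lm <- stats::lm(log2(ndufb8) ~ log2(vdac1), data = ctrl_fibers)

# draw a class factor directly from given proportions (bypasses the QIF
# generator where only class-level resampling behaviour is under test)
random_classes <- function(n, p_low, p_high, seed = NULL) {
  probs <- c(low = p_low, normal = 1 - p_low - p_high, high = p_high)
  cls <- myoxphos:::with_seed(seed,
    sample(names(probs), n, replace = TRUE, prob = probs))
  factor(cls, levels = c("low", "normal", "high"))
}
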