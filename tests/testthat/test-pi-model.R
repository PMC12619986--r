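test_that("pi model matches the independent lm() fit on the same controls", {
  expect_equal(unname(coef(ctrl_model)),
               unname(coef(ctrl_lm)), tolerance = 1e-10)
  expect_equal(ctrl_model$resid_sd, summary(ctrl_lm)$sigma, tolerance = 1e-10)

  # prediction bounds agree with predict.lm's prediction interval
  new <- data.frame(vdac1 = ctrl_fibers$vdac1[1:50])
  ours <- predict(ctrl_model, new)
  ref <- predict(ctrl_lm, data.frame(vdac1 = new$vdac1),
                 interval = "prediction", level = 0.95)
  expect_equal(ours$fit, unname(ref[, "fit"]), tolerance = 1e-10)
  expect_equal(ours$lwr, unname(ref[, "lwr"]), tolerance = 1e-10)
  expect_equal(ours$upr, unname(ref[, "upr"]), tolerance = 1e-10)
})

test_that("fit recovers the generating slope within 3 SE", {
  se_slope <- summary(ctrl_model)$se[["slope"]]
  expect_lt(abs(ctrl_model$slope - 1), 3 * se_slope)
})

test_that("degenerate control inputs are rejected", {
  flat <- data.frame(vdac1 = rep(8, 10), ndufb8 = stats::rnorm(10, 8))
  expect_error(fit_pi_model(flat, "ndufb8"), "zero spread")
  expect_error(fit_pi_model(ctrl_fibers[1:2, ], "ndufb8"), "at least 3")
})

test_that("exactly collinear controls give a vanishing interval and exact slope", {
  x <- 2^seq(6, 10, length.out = 30)
  fib <- data.frame(vdac1 = x, ndufb8 = 2^(0.3 + 0.8 * log2(x)))
  m <- fit_pi_model(fib, "ndufb8")
  expect_equal(m$slope, 0.8, tolerance = 1e-9)
  expect_equal(m$intercept, 0.3, tolerance = 1e-9)
  pr <- predict(m, fib)
  expect_lt(max(pr$upr - pr$lwr), 1e-6)
})

test_that("fibers are classified low/normal/high against the interval", {
  # a fiber exactly on the regression line is normal
  x <- 2^9
  on_line <- data.frame(
    vdac1 = x, ndufb8 = 2^(ctrl_model$intercept + ctrl_model$slope * log2(x)))
  expect_identical(as.character(classify_fibers(ctrl_model, on_line)), "normal")

  # far below the lower bound -> low; far above -> high
  pr <- predict(ctrl_model, on_line)
  hw <- (pr$upr - pr$lwr) / 2
  shifted <- data.frame(vdac1 = rep(x, 2),
                        ndufb8 = 2^(pr$fit + c(-10, 10) * hw))
  expect_identical(as.character(classify_fibers(ctrl_model, shifted)),
                   c("low", "high"))

  # a fiber exactly on a bound counts as normal (conservative tie rule);
  # checked on a raw-scale model so the bound value is representable exactly
  set.seed(2)
  xr <- stats::runif(50, 5, 10)
  raw <- data.frame(vdac1 = xr, ndufb8 = 2 + 0.5 * xr + stats::rnorm(50, 0, 0.3))
  mr <- fit_pi_model(raw, "ndufb8", transform = "none")
  prb <- predict(mr, data.frame(vdac1 = 7))
  on_bounds <- data.frame(vdac1 = c(7, 7), ndufb8 = c(prb$lwr, prb$upr))
  expect_identical(as.character(classify_fibers(mr, on_bounds)),
                   c("normal", "normal"))
})

test_that("non-positive intensities are QC-excluded, not imputed", {
  bad <- data.frame(vdac1 = c(500, -1, 600), ndufb8 = c(400, 500, 0))
  cls <- classify_fibers(ctrl_model, bad)
  expect_identical(is.na(cls), c(FALSE, TRUE, TRUE))
  expect_identical(attr(cls, "n_flagged"), 2L)
})

test_that("held-out coverage is close to the nominal 95%", {
  ho <- simulate(ctrl_model, 4000, seed = 5)
  cls <- classify_fibers(ctrl_model, ho)
  cov <- mean(cls == "normal")
  se <- sqrt(0.95 * 0.05 / 4000)
  expect_lt(abs(cov - 0.95), 4 * se + 0.005)
})

test_that("classification is invariant to common positive rescaling of intensities", {
  test <- generate_fiber_population(
    fiber_population_spec(300, frac_low = 0.15, frac_high = 0.1,
                          low_shift = -2, high_shift = 2, seed = 12))
  cls <- classify_fibers(ctrl_model, test)

  scale <- 7.3
  ctrl2 <- ctrl_fibers
  ctrl2$vdac1 <- ctrl2$vdac1 * scale
  ctrl2$ndufb8 <- ctrl2$ndufb8 * scale
  m2 <- fit_pi_model(ctrl2, "ndufb8")
  test2 <- test
  test2$vdac1 <- test2$vdac1 * scale
  test2$ndufb8 <- test2$ndufb8 * scale
  expect_identical(as.character(classify_fibers(m2, test2)),
                   as.character(cls))
})

test_that("class proportions and deltas follow the counting rules", {
  cls <- factor(c("low", "low", "high", "normal"),
                levels = c("low", "normal", "high"))
  p <- class_proportions(cls)
  expect_equal(c(p$p_low, p$p_normal, p$p_high), c(0.5, 0.25, 0.25))
  expect_equal(p$p_low + p$p_normal + p$p_high, 1)

  all_norm <- class_proportions(factor(rep("normal", 10),
                                       levels = c("low", "normal", "high")))
  expect_equal(c(all_norm$p_low, all_norm$p_normal, all_norm$p_high),
               c(0, 1, 0))
  expect_error(class_proportions(factor(character(), levels = "normal")),
               "no classified fibers")

  # brute-force counting oracle on random labels
  set.seed(33)
  lab <- random_classes(500, 0.2, 0.3, seed = 33)
  p2 <- class_proportions(lab)
  expect_equal(p2$p_high, sum(lab == "high") / 500)
  expect_equal(p2$p_low, sum(lab == "low") / 500)

  # deltas
  d <- delta_proportions(p, p)
  expect_equal(c(d$delta_high, d$delta_low), c(0, 0))
  pre <- class_proportions(random_classes(200, 0.1, 0.1, seed = 1))
  post <- class_proportions(random_classes(200, 0.1, 0.4, seed = 2))
  expect_equal(delta_proportions(pre, post)$delta_high,
               post$p_high - pre$p_high)
})

test_that("deltas refuse proportions classified under different models", {
  m_b <- fit_pi_model(ctrl_fibers[1:1000, ], "ndufb8")
  test <- generate_fiber_population(fiber_population_spec(100, seed = 13))
  p1 <- class_proportions(classify_fibers(ctrl_model, test))
  p2 <- class_proportions(classify_fibers(m_b, test))
  expect_error(delta_proportions(p1, p2), "different models")
})

test_that("simulate() round-trips through the raw scale", {
  sim <- simulate(ctrl_model, 500, seed = 6)
  expect_true(all(sim$vdac1 > 0 & sim$ndufb8 > 0))
  expect_identical(simulate(ctrl_model, 50, seed = 7),
                   simulate(ctrl_model, 50, seed = 7))
  # conditioning on given mass values
  sim2 <- simulate(ctrl_model, 5, seed = 8, newmass = rep(512, 5))
  expect_equal(sim2$vdac1, rep(512, 5))
})
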