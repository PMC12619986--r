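# explicit label-resampling oracles, kept independent of the package's
# count-based implementations
boot_oracle <- function(pre, post, B, seed) {
  set.seed(seed)
  reps <- replicate(B, {
    bp <- sample(pre, replace = TRUE)
    bq <- sample(post, replace = TRUE)
    c(mean(bq == "high") - mean(bp == "high"),
      mean(bq == "low") - mean(bp == "low"))
  })
  list(ci_high = unname(stats::quantile(reps[1, ], c(0.025, 0.975))),
       ci_low = unname(stats::quantile(reps[2, ], c(0.025, 0.975))))
}

perm_oracle <- function(pre, post, n_perm, seed) {
  set.seed(seed)
  n_pre <- length(pre)
  pool <- c(as.character(pre), as.character(post))
  d_obs <- mean(post == "high") - mean(pre == "high")
  d_null <- replicate(n_perm, {
    idx <- sample(length(pool), n_pre)
    mean(pool[-idx] == "high") - mean(pool[idx] == "high")
  })
  (1 + sum(abs(d_null) >= abs(d_obs) - 1e-12)) / (n_perm + 1)
}

test_that("bootstrap deltas are reproducible and handle degenerate inputs", {
  cls <- random_classes(300, 0.15, 0.2, seed = 61)
  b1 <- bootstrap_delta(cls, cls, B = 500, seed = 1)
  b2 <- bootstrap_delta(cls, cls, B = 500, seed = 1)
  expect_identical(b1, b2)

  # same fibers pre and post: point estimate 0, CI centered near 0
  expect_equal(b1$delta_high, 0)
  expect_lt(abs(mean(b1$ci_high)), 0.05)
  expect_true(b1$ci_high[1] <= 0 && b1$ci_high[2] >= 0)

  # single-class populations collapse the CI to [0, 0]
  mono <- factor(rep("normal", 50), levels = c("low", "normal", "high"))
  b3 <- bootstrap_delta(mono, mono, B = 100, seed = 2)
  expect_identical(unname(b3$ci_high), c(0, 0))
  expect_identical(unname(b3$ci_low), c(0, 0))

  expect_error(bootstrap_delta(cls, cls, B = 50), "at least 100")
  empty <- factor(character(), levels = c("low", "normal", "high"))
  expect_error(bootstrap_delta(empty, cls), "no classified fibers")
})

test_that("count-based bootstrap matches explicit label resampling", {
  pre <- random_classes(400, 0.1, 0.1, seed = 62)
  post <- random_classes(350, 0.1, 0.3, seed = 63)
  ours <- bootstrap_delta(pre, post, B = 4000, seed = 3)
  ref <- boot_oracle(pre, post, B = 4000, seed = 4)
  expect_equal(ours$ci_high, ref$ci_high, tolerance = 0.02)
  expect_equal(ours$ci_low, ref$ci_low, tolerance = 0.02)
  # CI contains the point estimate
  expect_true(ours$ci_high[1] <= ours$delta_high &&
                ours$delta_high <= ours$ci_high[2])
})

test_that("permutation p follows the add-one rule and its exact null", {
  cls <- random_classes(200, 0.1, 0.15, seed = 64)
  # identical pre/post: observed delta 0 -> p = 1 exactly
  p_same <- permutation_test_delta(cls, cls, n_perm = 199, seed = 5)
  expect_equal(p_same$p_high, 1)
  expect_equal(p_same$p_low, 1)
  expect_equal(p_same$delta_high, 0)

  # degenerate pool (all one class) -> p = 1 by convention
  mono <- factor(rep("normal", 40), levels = c("low", "normal", "high"))
  expect_equal(permutation_test_delta(mono, mono, n_perm = 99, seed = 6)$p_high, 1)

  # p never 0, never above 1, reproducible under seed
  pre <- random_classes(150, 0.05, 0.05, seed = 65)
  post <- random_classes(150, 0.05, 0.45, seed = 66)
  pt <- permutation_test_delta(pre, post, n_perm = 999, seed = 7)
  expect_gte(pt$p_high, 1 / 1000)
  expect_lte(pt$p_high, 1)
  expect_identical(pt, permutation_test_delta(pre, post, n_perm = 999, seed = 7))
  expect_identical(pt$null, "pooled_resplit")

  # agrees with the exact hypergeometric tail of the pooled re-split null
  tot_high <- sum(pre == "high") + sum(post == "high")
  N <- length(pre) + length(post)
  supp <- 0:tot_high
  d_obs <- sum(post == "high") * length(pre) - sum(pre == "high") * length(post)
  d_sup <- supp * length(pre) - (tot_high - supp) * length(post)
  p_exact <- sum(stats::dhyper(supp, tot_high, N - tot_high,
                               length(post))[abs(d_sup) >= abs(d_obs)])
  expect_equal(pt$p_high, p_exact, tolerance = 0.02)
})

test_that("hypergeometric null matches brute-force pooled re-splitting", {
  pre <- random_classes(120, 0.1, 0.2, seed = 67)
  post <- random_classes(100, 0.1, 0.35, seed = 68)
  ours <- permutation_test_delta(pre, post, n_perm = 4999, seed = 8)
  ref <- perm_oracle(pre, post, n_perm = 2000, seed = 9)
  expect_equal(ours$p_high, ref, tolerance = 0.03)
})

test_that("BH adjustment reproduces the hand-computed step-up", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(0.3), 0.3)            # single p: q = p
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))

  # manual step-up oracle on random p-values
  set.seed(71)
  p <- stats::runif(20)
  ord <- order(p, decreasing = TRUE)
  manual <- numeric(20)
  running <- 1
  for (i in seq_along(ord)) {
    k <- ord[i]
    running <- min(running, p[k] * 20 / rank(p)[k])
    manual[k] <- running
  }
  q <- fdr_adjust(p)
  expect_equal(q, manual)
  # never decreases p, preserves ranking (ties allowed)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= 0))

  expect_error(fdr_adjust(c(0.1, 0)), "\\(0, 1\\]")
  expect_error(fdr_adjust(c(0.1, 1.2)), "\\(0, 1\\]")
})

test_that("direction-plus-significance calls follow the study rule", {
  expect_identical(call_significance(0.3, 0.01, "high"),
                   "significant_increase_high")
  expect_identical(call_significance(0.3, 0.20, "high"), "ns")
  expect_identical(call_significance(-0.3, 0.01, "high"),
                   "significant_negative_change")
  expect_identical(call_significance(-0.2, 0.01, "low"),
                   "significant_decrease_low")
  # a significant INCREASE in deficient fibers is a negative change
  expect_identical(call_significance(0.2, 0.01, "low"),
                   "significant_negative_change")
  expect_identical(call_significance(-0.2, 0.30, "low"), "ns")
  # vectorized
  expect_identical(call_significance(c(0.3, -0.3), c(0.01, 0.01), "high"),
                   c("significant_increase_high", "significant_negative_change"))
})

test_that("bonferroni mean tests clamp at 1 and leave k = 1 unchanged", {
  set.seed(72)
  x <- stats::rnorm(8); y <- stats::rnorm(8, 1)
  one <- bonferroni_mean_tests(x, y, k = 1)
  expect_equal(one$p_adjusted, one$p_value)
  expect_equal(bonferroni_mean_tests(x, y, k = 3)$p_adjusted,
               min(1, 3 * one$p_value))
  z <- stats::rnorm(8)
  many <- bonferroni_mean_tests(x, z, k = 50)
  expect_lte(many$p_adjusted, 1)
  expect_error(bonferroni_mean_tests(x, y, k = 0), ">= 1")
})

test_that("delta_test recovers responders and spares nulls (joint study)", {
  ctrl <- generate_fiber_population(fiber_population_spec(2000, seed = 81),
                                    timepoint = "unaffected")
  model <- fit_pi_model(ctrl, "ndufb8")
  n_rep <- 100
  ok_resp <- numeric(n_rep); false_calls <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    res <- lapply(1:6, function(i) {
      frac_post <- if (i <= 3) 0.30 else 0.05   # 3 responders, 3 nulls
      pre <- generate_fiber_population(fiber_population_spec(
        300, frac_high = 0.05, high_shift = 3, seed = 8000 + r * 13 + i))
      post <- generate_fiber_population(fiber_population_spec(
        300, frac_high = frac_post, high_shift = 3, seed = 9000 + r * 17 + i))
      delta_test(classify_fibers(model, pre), classify_fibers(model, post),
                 B = 200, n_perm = 999, seed = 700 + r * 29 + i)
    })
    res <- do.call(rbind, res)
    q <- fdr_adjust(c(res$p_perm_high, res$p_perm_low))
    q_high <- q[1:6]; q_low <- q[7:12]
    call_high <- call_significance(res$delta_high, q_high, "high")
    call_low <- call_significance(res$delta_low, q_low, "low")
    ok_resp[r] <- sum(call_high[1:3] == "significant_increase_high")
    false_calls[r] <- sum(call_high[4:6] != "ns") + sum(call_low[4:6] != "ns")
  }
  expect_gte(mean(ok_resp) / 3, 0.9)              # sensitivity
  expect_gte(mean(false_calls == 0), 0.9)         # specificity per replicate
})
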