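test_that("fiber population spec validates its invariants", {
  expect_error(fiber_population_spec(0), "positive integer")
  expect_error(fiber_population_spec(100, frac_low = 0.6, frac_high = 0.5),
               "must not exceed 1")
  expect_error(fiber_population_spec(100, frac_low = 1.2), "\\[0, 1\\]")
  expect_error(fiber_population_spec(100, low_shift = 1), "low_shift")
  expect_error(fiber_population_spec(100, high_shift = -1), "high_shift")
  expect_error(fiber_population_spec(100, mass_sd = 0), "mass_sd")
  expect_error(fiber_population_spec(100, resid_sd = -0.1), "resid_sd")
})

test_that("noiseless fiber population lies exactly on the control line", {
  spec <- fiber_population_spec(50, slope = 1.2, intercept = -1,
                                resid_sd = 0, seed = 1)
  fib <- generate_fiber_population(spec)
  expect_equal(log2(fib$ndufb8), -1 + 1.2 * log2(fib$vdac1))
  expect_equal(log2(fib$mtco1), -1 + 1.2 * log2(fib$vdac1))
  expect_true(all(fib$true_class == "normal"))
})

test_that("class counts follow the rounding rule exactly", {
  fib <- generate_fiber_population(
    fiber_population_spec(1000, frac_low = 0.3, seed = 7))
  expect_identical(sum(fib$true_class == "low"), 300L)
  expect_identical(sum(fib$true_class == "high"), 0L)

  fib2 <- generate_fiber_population(
    fiber_population_spec(333, frac_low = 0.1, frac_high = 0.25, seed = 8))
  expect_identical(sum(fib2$true_class == "low"), 33L)
  expect_identical(sum(fib2$true_class == "high"), 83L)
})

test_that("generated controls refit to the generating line within 3 SE", {
  spec <- fiber_population_spec(4000, slope = 0.9, intercept = 0.5,
                                resid_sd = 0.2, seed = 11)
  fib <- generate_fiber_population(spec, timepoint = "unaffected")
  fit <- stats::lm(log2(ndufb8) ~ log2(vdac1), data = fib)
  se <- summary(fit)$coefficients[, "Std. Error"]
  expect_lt(abs(coef(fit)[[2]] - 0.9), 3 * se[[2]])
  expect_lt(abs(coef(fit)[[1]] - 0.5), 3 * se[[1]])
  # residual scale recovered too
  expect_equal(summary(fit)$sigma, 0.2, tolerance = 0.05)
})

test_that("fixed seed gives bit-identical generator output", {
  s <- fiber_population_spec(200, frac_low = 0.1, seed = 42)
  expect_identical(generate_fiber_population(s), generate_fiber_population(s))
  ts <- trace_spec(noise_sd = 0.3, seed = 42)
  expect_identical(generate_trace(ts), generate_trace(ts))
  expect_identical(
    generate_histology_table(500, seed = 42),
    generate_histology_table(500, seed = 42))
  expect_identical(
    generate_calibration_series(0:5, noise_sd = 0.1, seed = 42),
    generate_calibration_series(0:5, noise_sd = 0.1, seed = 42))
})

test_that("generators restore the caller's RNG stream", {
  set.seed(1); before <- .Random.seed
  invisible(generate_fiber_population(fiber_population_spec(10, seed = 9)))
  invisible(generate_trace(trace_spec(noise_sd = 1, seed = 9)))
  expect_identical(.Random.seed, before)
})

test_that("trace spec rejects malformed protocols", {
  pr <- suit_protocol()
  pr$time_s[2] <- pr$time_s[1]
  expect_error(trace_spec(pr), "overlap|increasing")
  pr2 <- suit_protocol()
  pr2$time_s <- rev(pr2$time_s)
  expect_error(trace_spec(pr2), "increasing")
  expect_error(trace_spec(wet_mass_mg = 0), "wet_mass_mg")
  expect_error(trace_spec(noise_sd = -1), "noise_sd")
})

test_that("noiseless trace slopes match the closed form", {
  pr <- suit_protocol(o2_fluxes = c(GM = 12), h2o2_rates = c(GM = 30))
  tr <- generate_trace(trace_spec(pr, wet_mass_mg = 4, chamber_volume_mL = 2,
                                  fluor_gain = 2))
  # O2 slope: -flux * mass / volume / 60 per second
  o2_slope <- coef(stats::lm(tr$o2_conc ~ tr$time))[[2]]
  expect_equal(o2_slope, -12 * 4 / 2 / 60, tolerance = 1e-12)
  fl_slope <- coef(stats::lm(tr$fluor ~ tr$time))[[2]]
  expect_equal(fl_slope, 2 * 30 * 4 / 2 / 60, tolerance = 1e-12)

  # all-zero fluxes give a flat O2 trace
  flat <- generate_trace(trace_spec(
    suit_protocol(o2_fluxes = c(GM = 0, ADP = 0),
                  h2o2_rates = c(GM = 0, ADP = 0))))
  expect_equal(diff(range(flat$o2_conc)), 0)
})

test_that("calibration series is exact without noise and rejects < 2 levels", {
  expect_error(generate_calibration_series(5), "2 distinct")
  expect_error(generate_calibration_series(c(3, 3)), "2 distinct")
  s <- generate_calibration_series(c(0, 1, 2), gain = 1, offset = 0)
  expect_equal(s$fluor, c(0, 1, 2))
  s2 <- generate_calibration_series(c(0, 2), gain = 2, offset = 5)
  expect_equal(s2$fluor, c(5, 9))
})

test_that("histology generator matches its Bernoulli and CSA structure", {
  zero <- generate_histology_table(
    200, marker_probs = c(ncam_pos = 0, central_nucleus = 0,
                          nuclear_clump = 0, damaged_laminin = 0), seed = 3)
  expect_false(any(zero$ncam_pos | zero$central_nucleus |
                     zero$nuclear_clump | zero$damaged_laminin))

  big <- generate_histology_table(
    10000, marker_probs = c(ncam_pos = 0.10, central_nucleus = 0.1,
                            nuclear_clump = 0.1, damaged_laminin = 0.1),
    seed = 4)
  p_hat <- mean(big$ncam_pos)
  expect_gt(p_hat, 0.085); expect_lt(p_hat, 0.115)

  # NCAM+ CSA contrast emulates the -17.8% atrophy target at large n
  expect_equal(csa_contrast(big$csa[big$ncam_pos], big$csa[!big$ncam_pos]),
               -17.8, tolerance = 0.15)
})

test_that("cohort fixture reproduces the printed per-participant rows", {
  coh <- cohort_fixture()
  expect_identical(nrow(coh), 18L)
  expect_identical(coh$ctg_repeats[coh$participant == "P3"], 832L)
  expect_identical(coh$ncam_pos_pct[coh$participant == "Unaffected_8"], 0)
  expect_identical(sum(!is.na(coh$ncam_pos_pct[coh$group == "unaffected"])), 7L)
  expect_true(all(is.na(coh$ctg_repeats[coh$group == "unaffected"])))
  # BMI consistent with weight/height within printed rounding
  bmi <- coh$weight_kg / (coh$height_cm / 100)^2
  expect_true(all(abs(bmi - coh$bmi_kg_m2) < 0.35))
})
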