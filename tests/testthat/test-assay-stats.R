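test_that("standard-curve fitting is exact on the calibration line", {
  # seven noiseless tenfold dilutions on Ct = -3.316 log10(copies) + 38.19
  copies <- 10^(1:7)
  ct <- -3.316 * log10(copies) + 38.19
  fit <- fit_standard_curve(copies, ct)
  expect_equal(fit$slope, -3.316, tolerance = 1e-12)
  expect_equal(fit$intercept, 38.19, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  # adding a constant shifts the intercept only
  fit2 <- fit_standard_curve(copies, ct + 2.5)
  expect_equal(fit2$slope, fit$slope, tolerance = 1e-12)
  expect_equal(fit2$intercept, fit$intercept + 2.5, tolerance = 1e-12)

  # closed-form normal-equations oracle on noisy data
  set.seed(4)
  for (i in 1:20) {
    cps <- 10^runif(8, 0, 7)
    y <- rnorm(8, 30, 3)
    f <- fit_standard_curve(cps, y)
    x <- log10(cps)
    b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    a <- mean(y) - b * mean(x)
    expect_equal(f$slope, b, tolerance = 1e-10)
    expect_equal(f$intercept, a, tolerance = 1e-10)
  }
  expect_error(fit_standard_curve(c(10, 100), c(30, 27)), "at least 3")
  expect_error(fit_standard_curve(c(10, -1, 100), c(1, 2, 3)), "> 0")
})

test_that("absolute quantification inverts the curve and the generator", {
  curve <- standard_curve(-3.316, 38.19)
  mk <- function(ct) qpcr_sample(ct, lysate_volume_ul = 10)
  # Ct at the intercept: one copy in the reaction
  expect_equal(quantify_absolute(mk(rep(38.19, 3)), curve)$copies_reaction, 1,
               tolerance = 1e-12)
  # one |slope| below the intercept: ten copies
  expect_equal(quantify_absolute(mk(rep(38.19 - 3.316, 3)), curve)$copies_reaction,
               10, tolerance = 1e-12)
  expect_error(quantify_absolute(mk(c(20, 21)), standard_curve(2, 30)),
               "negative")

  # noiseless generator round trip recovers copies per worm exactly
  true_per_worm <- 3.8e6
  # copies in the reaction implied by the sample geometry
  reaction <- true_per_worm * 5 / (40 * (10 / 2))
  run <- simulate_qpcr_run(reaction, curve, ct_noise_sd = 0, replicates = 3,
                           seed = 2)
  smp <- qpcr_sample(run$ct, lysate_volume_ul = 10)
  est <- quantify_absolute(smp, curve)
  expect_equal(est$copies_per_worm, true_per_worm, tolerance = 1e-9)
})

test_that("relative quantification scales by the curve and covers the truth", {
  curve <- standard_curve(-3.316, 38.19)
  ref <- qpcr_sample(c(20.0, 20.2, 19.8), lysate_volume_ul = 10, id = "ctrl")
  # the reference against itself: exactly 100% with a CI containing 100
  self <- quantify_relative(ref, ref, curve)
  expect_equal(self$percent, 100)
  expect_lte(self$ci_lower, 100); expect_gte(self$ci_upper, 100)

  # a +|slope| cycle shift means tenfold fewer copies: 10% of reference
  shifted <- qpcr_sample(ref$ct_values + 3.316, lysate_volume_ul = 10)
  expect_equal(quantify_relative(shifted, ref, curve)$percent, 10,
               tolerance = 1e-9)

  # Monte-Carlo coverage: the CI contains the true ratio ~95/100 times
  hits <- 0
  for (s in 1:100) {
    run <- withr::with_seed(s, {
      list(smp = rnorm(9, 24.0, 0.2), ref = rnorm(9, 23.0, 0.2))
    })
    q <- quantify_relative(qpcr_sample(run$smp, lysate_volume_ul = 10),
                           qpcr_sample(run$ref, lysate_volume_ul = 10), curve)
    true_pct <- 100 * 10^((24 - 23) / curve$slope)
    expect_equal(q$df, 16)
    if (q$ci_lower <= true_pct && true_pct <= q$ci_upper) hits <- hits + 1
  }
  expect_gte(hits, 88)
})

test_that("pooled t-test matches hand computation and the reference oracle", {
  # identical groups
  same <- pooled_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  # hand-computed example: s_p = 1, t = -1/sqrt(2/3)
  ex <- pooled_t_test(c(1, 2, 3), c(2, 3, 4))
  expect_equal(ex$s_p, 1, tolerance = 1e-12)
  expect_equal(ex$statistic, -1 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(ex$df, 4)

  # group exchange flips the sign only
  swap <- pooled_t_test(c(2, 3, 4), c(1, 2, 3))
  expect_equal(swap$statistic, -ex$statistic, tolerance = 1e-12)
  expect_equal(swap$p_value, ex$p_value, tolerance = 1e-12)

  # matches t.test(var.equal = TRUE) to 1e-10 on 1000 random pairs
  set.seed(6)
  for (i in 1:1000) {
    g1 <- rnorm(sample(3:12, 1), 0, runif(1, 0.5, 3))
    g2 <- rnorm(sample(3:12, 1), runif(1, -1, 1), runif(1, 0.5, 3))
    mine <- pooled_t_test(g1, g2)
    ref <- t.test(g1, g2, var.equal = TRUE)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
  }
  expect_error(pooled_t_test(1, c(1, 2)), "at least 2")

  # zero pooled variance with different means: flagged infinite statistic
  degen <- pooled_t_test(c(2, 2, 2), c(3, 3, 3))
  expect_true(degen$degenerate)
  expect_equal(degen$statistic, -Inf)
})

test_that("variance F-test is symmetric and matches var.test", {
  eq <- f_test_variances(c(1, 2, 3, 4), c(10, 11, 12, 13))
  expect_equal(eq$statistic, 1)
  expect_equal(eq$p_value, 1)

  set.seed(9)
  g1 <- rnorm(8, 0, 1); g2 <- rnorm(8, 0, 3)
  a <- f_test_variances(g1, g2)
  b <- f_test_variances(g2, g1)
  expect_equal(a$statistic, b$statistic, tolerance = 1e-12)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
  # equal group sizes: agrees with stats::var.test
  expect_equal(a$p_value, var.test(g1, g2)$p.value, tolerance = 1e-10)
  expect_false(a$equal_variance)
  expect_error(f_test_variances(c(1, 1, 1), g2), "variance")
})

test_that("respiration rate finds the straight window", {
  # exact line, protein 1 mg
  tr <- simulate_o2_trace(0.5, noise_sd = 0)
  r <- respiration_rate(tr$time_min, tr$o2, protein_mg = 1)
  expect_equal(r$rate, 0.5, tolerance = 1e-12)
  expect_equal(r$window, c(1, nrow(tr)))

  # doubling protein halves the rate
  r2 <- respiration_rate(tr$time_min, tr$o2, protein_mg = 2)
  expect_equal(r2$rate, r$rate / 2, tolerance = 1e-12)

  # nonlinear equilibration start is excluded; rate within 1% of truth
  tre <- simulate_o2_trace(0.5, equilibration = TRUE, noise_sd = 0.01,
                           seed = 2)
  re <- respiration_rate(tre$time_min, tre$o2, protein_mg = 1)
  expect_equal(re$rate, 0.5, tolerance = 0.01)
  expect_gt(re$window[1], 1)

  # an increasing trace is flagged
  up <- simulate_o2_trace(-0.3, noise_sd = 0)
  expect_warning(ru <- respiration_rate(up$time_min, up$o2, 1), "increases")
  expect_true(ru$increasing_flag)
  expect_error(respiration_rate(1:5, 5:1, 1), "10 points")
})

test_that("redox ratio behaves as a percentage of the pool", {
  expect_equal(redox_ratio(3, 3), 50)
  expect_equal(redox_ratio(7, 0), 100)
  expect_equal(redox_ratio(0, 2), 0)
  expect_equal(redox_ratio(2 * 4.2, 2 * 1.8), redox_ratio(4.2, 1.8))
  expect_equal(redox_ratio(c(1, 1), c(1, 3)), c(50, 25))
  expect_error(redox_ratio(0, 0), "zero")
  expect_error(redox_ratio(-1, 2), "non-negative")
})
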