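test_that("stepwise logistic keeps real predictors and drops noise", {
  # CASI drives CPSP risk, preoperative pain does not: the reduced model
  # retains CASI only
  set.seed(64)
  n <- 300
  casi <- rnorm(n, 28.6, 5.5)
  preop <- ifelse(runif(n) < 0.75, 0, sample(1:5, n, replace = TRUE))
  p <- plogis(-4.3 + 0.15 * casi)
  d <- data.frame(cpsp = rbinom(n, 1, p), casi = casi, preop_pain = preop)
  fit <- fit_stepwise_logistic(d, c("casi", "preop_pain"))
  expect_setequal(fit$terms$term, c("(Intercept)", "casi"))
  expect_gt(fit$terms$or[fit$terms$term == "casi"], 1)
  expect_equal(fit$terms$or, exp(fit$terms$estimate))
})

test_that("stepwise returns intercept-only when no candidate qualifies", {
  io <- vapply(1:50, function(s) {
    set.seed(s)
    d <- data.frame(cpsp = rbinom(300, 1, 0.4), a = rnorm(300), b = rnorm(300))
    nrow(fit_stepwise_logistic(d, c("a", "b"))$terms) == 1
  }, logical(1))
  expect_gte(mean(io), 0.9)
})

test_that("stepwise reports perfect separation instead of a silent fit", {
  d <- data.frame(cpsp = rep(c(0L, 1L), each = 20), x = rep(c(0, 10), each = 20))
  expect_error(fit_stepwise_logistic(d, "x"), "separation")
})

test_that("AUC matches the exhaustive pairwise oracle, including ties", {
  set.seed(62)
  for (i in 1:6) {
    n <- sample(10:50, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0L, 1L)
    sc <- round(rnorm(n), 1)  # rounding forces ties
    expect_equal(roc_auc(sc, y)$auc, auc_oracle(sc, y))
  }
  # perfect and inverted predictors
  y <- rep(c(0L, 1L), each = 10)
  expect_equal(roc_auc(seq_len(20), y)$auc, 1)
  expect_equal(roc_auc(rev(seq_len(20)), y)$auc, 0)
  expect_error(roc_auc(rnorm(5), rep(1L, 5)), "classes")
})

test_that("AUC of random scores is near one half at n = 2000", {
  set.seed(63)
  auc <- roc_auc(rnorm(2000), rbinom(2000, 1, 0.4))$auc
  expect_lt(abs(auc - 0.5), 0.03)
})

test_that("paired AUC comparison detects a planted PRS effect and has p = 1 on ties", {
  set.seed(64)
  wins <- logical(50)
  for (s in 1:50) {
    set.seed(s)
    n <- 300
    casi <- rnorm(n, 28.6, 5.5)
    prs <- rnorm(n, 21, 4)
    p <- plogis(-20 + 0.15 * casi + 0.7 * prs)
    d <- data.frame(cpsp = rbinom(n, 1, p), casi = casi, prs = prs)
    clin <- fit_stepwise_logistic(d, "casi")
    gen <- fit_stepwise_logistic(d, c("casi", "prs"))
    wins[s] <- compare_auc(gen, clin)$p_value < 0.05
  }
  expect_gte(mean(wins), 0.9)
  # identical scores: difference is exactly zero
  d <- data.frame(cpsp = rbinom(100, 1, 0.4), x = rnorm(100))
  f <- fit_stepwise_logistic(d, character(0))
  expect_equal(compare_auc(f, f)$p_value, 1)
  # mismatched individuals are rejected in paired mode
  d2 <- d; d2$cpsp <- rev(d2$cpsp)
  f2 <- fit_stepwise_logistic(d2, character(0))
  expect_error(compare_auc(f, f2), "same individuals")
})

test_that("probability curve is monotone with a closed-form 50% crossing", {
  set.seed(65)
  n <- 400
  casi <- rnorm(n, 28.6, 5.5)
  prs <- rnorm(n, 21, 4)
  p <- plogis(-18 + 0.12 * casi + 0.65 * prs)
  d <- data.frame(cpsp = rbinom(n, 1, p), casi = casi, prs = prs)
  fit <- fit_stepwise_logistic(d, c("casi", "prs"))
  grid <- seq(5, 35, by = 0.01)
  curve <- probability_curve(fit, grid, casi_fixed = 28.3)
  expect_true(all(diff(curve$probability) > 0))
  expect_true(all(curve$lower <= curve$probability &
                  curve$probability <= curve$upper))
  crossing <- attr(curve, "crossing_prs")
  # grid-search oracle for the 50% crossing
  oracle <- grid[which.min(abs(curve$probability - 0.5))]
  expect_lt(abs(crossing - oracle), 0.011)
  # a grid point at the crossing has probability one half
  at <- probability_curve(fit, crossing, casi_fixed = 28.3)
  expect_equal(at$probability, 0.5, tolerance = 1e-8)
})

test_that("bootstrap bias correction satisfies its defining identity", {
  set.seed(66)
  n <- 131
  casi <- rnorm(n, 28.6, 5.5)
  prs <- rnorm(n, 21, 4)
  p <- plogis(-18 + 0.12 * casi + 0.65 * prs)
  ph <- data.frame(cpsp = rbinom(n, 1, p), casi = casi, prs = prs)
  bs <- bootstrap_validate(ph, c("casi", "prs"), n_boot = 300, seed = 9)
  expect_equal(bs$corrected, bs$original - bs$bias)
  expect_equal(bs$bias, bs$boot_mean - bs$original)
  expect_equal(bs$or_corrected, exp(bs$corrected))
  # seed-fixed reproducibility
  bs2 <- bootstrap_validate(ph, c("casi", "prs"), n_boot = 300, seed = 9)
  expect_identical(as.data.frame(bs), as.data.frame(bs2))
})

test_that("degenerate two-point bootstrap has zero bias by construction", {
  d <- data.frame(cpsp = c(0L, 1L), x = c(0, 1))
  bs <- suppressWarnings(bootstrap_validate(d, "x", n_boot = 50, seed = 2))
  # every valid resample contains both rows once: bootstrap mean = original
  expect_equal(bs$bias, rep(0, 2), tolerance = 1e-8)
  expect_equal(bs$corrected, bs$original, tolerance = 1e-8)
})

test_that("closed-form power calculations behave at their boundaries", {
  expect_equal(power_two_proportions(0.1, 0.1, 500), 0.05, tolerance = 1e-10)
  expect_gt(power_two_proportions(0.05, 0.064, 1e6), 0.999)
  expect_equal(power_two_means(0, 4, 52, 79), 0.05, tolerance = 1e-10)
  expect_gt(power_two_means(2, 0.05, 52, 79), 0.999)
  expect_equal(proportion_or(0.3, 0.3), 1)
  expect_equal(proportion_or(0.5, 2 / 3), 2)
  expect_error(proportion_or(0, 0.5), "p0")
})

test_that("closed-form power matches Monte-Carlo simulation", {
  # two-proportion, one-sided
  set.seed(67)
  p0 <- 0.05; p1 <- 0.08; n <- 1500
  closed <- power_two_proportions(p0, p1, n, one_sided = TRUE)
  rej <- vapply(1:4000, function(i) {
    x0 <- rbinom(1, n, p0); x1 <- rbinom(1, n, p1)
    suppressWarnings(prop.test(c(x1, x0), c(n, n), alternative = "greater",
                               correct = FALSE)$p.value) < 0.05
  }, logical(1))
  expect_lt(abs(closed - mean(rej)), 0.02)
  # two-mean, two-sided
  closed2 <- power_two_means(2, 4, 52, 79)
  rej2 <- vapply(1:4000, function(i) {
    t.test(rnorm(52, 2, 4), rnorm(79, 0, 4))$p.value < 0.05
  }, logical(1))
  expect_lt(abs(closed2 - mean(rej2)), 0.02)
})

test_that("Monte-Carlo variant power is calibrated at the null and saturates", {
  expect_lt(abs(power_variant_or(1, 0.4, 53, 78, n_reps = 2000, seed = 2) - 0.05),
            0.02)
  expect_gt(power_variant_or(10, 0.4, 53, 78, n_reps = 500, seed = 3), 0.99)
  expect_error(power_variant_or(2, 0.4, 53, 78, n_reps = 50), "100")
})
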