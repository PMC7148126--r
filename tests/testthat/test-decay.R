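test_that("fitSinglePhase recovers exact slopes and half-lives", {
  f <- fitSinglePhase(c(0, 1, 2), c(-20, -21, -22))
  expect_equal(decaySlope(f), -1)
  expect_equal(halfLife(f), 1)
  f2 <- fitSinglePhase(c(0, 1), c(-20, -23))
  expect_equal(decaySlope(f2), -3)
  expect_equal(halfLife(f2), 1 / 3)
  expect_null(f2@ci95_half_life)   # two points, no residual df
  # noiseless exponential with t1/2 = 0.6 min at the standard chase times
  t <- c(0, 1, 2, 4)
  f3 <- fitSinglePhase(t, -20 - t / 0.6)
  expect_equal(halfLife(f3), 0.6, tolerance = 1e-9)
  expect_equal(f3@r2, 1)
})

test_that("half-life identity and sentinel behavior", {
  set.seed(11)
  for (i in 1:20) {
    t <- rep(c(0, 1, 2, 4), each = 2)
    y <- -20 - t / runif(1, 0.2, 5) + rnorm(length(t), 0, 0.2)
    f <- fitSinglePhase(t, y)
    if (decaySlope(f) < 0)
      expect_equal(halfLife(f) * (-decaySlope(f)), 1, tolerance = 1e-12)
  }
  expect_warning(f <- fitSinglePhase(c(0, 1, 2), c(-20, -19.5, -19)),
                 "infinite half-life")
  expect_identical(halfLife(f), Inf)
  expect_error(fitSinglePhase(c(1, 1), c(0, 1)), "distinct")
})

test_that("half-life CI comes from inverting the slope CI", {
  t <- rep(c(0, 1, 2, 4), each = 3)
  set.seed(3)
  y <- -20 - t / 1.5 + rnorm(length(t), 0, 0.1)
  f <- fitSinglePhase(t, y)
  sci <- confint(lm(y ~ t), "t")
  expect_equal(f@ci95_half_life, sort(c(-1 / sci[1], -1 / sci[2])))
  expect_true(f@ci95_half_life[1] < halfLife(f),
              f@ci95_half_life[2] > halfLife(f))
})

test_that("single exponentials are not classified biphasic", {
  t <- rep(c(0, 1, 2, 4), each = 3)
  fit <- segmentBiphasic(t, -20 - t / 1.5)
  expect_false(isBiphasic(fit))
  expect_identical(fastFraction(fit), 1)
  expect_equal(halfLife(fit), 1.5, tolerance = 1e-9)
  expect_null(slowPhase(fit))
})

test_that("degenerate and short inputs fall back to single phase with warning", {
  t <- rep(c(0, 1, 2, 4), each = 2)
  expect_warning(fit <- segmentBiphasic(t, rep(-20, length(t))),
                 "abundances equal")
  expect_false(isBiphasic(fit))
  expect_equal(decaySlope(fit), 0)
  expect_warning(fit2 <- segmentBiphasic(c(0, 1, 2), c(-20, -22, -22.5)),
                 "single-phase")
  expect_false(isBiphasic(fit2))
})

test_that("two-pool mixture segmentation matches the brute-force SSE oracle", {
  # 95% fast pool (t1/2 0.5 min) + 5% slow pool (t1/2 20 min), dense noiseless
  tt <- seq(0, 4, by = 0.1)
  y <- log2(0.95 * 2^(-tt / 0.5) + 0.05 * 2^(-tt / 20))
  fit <- segmentBiphasic(tt, y)
  oracle <- brute_force_segments(tt, y)
  expect_true(isBiphasic(fit))
  expect_identical(fit@breakpoint_index, as.integer(oracle$b))
  expect_equal(decaySlope(fit), oracle$fast_slope, tolerance = 1e-10)
  expect_equal(fastFraction(fit),
               1 - 2^(oracle$slow_int - oracle$fast_int), tolerance = 1e-10)
  # frozen oracle values for this curve: the 4-min window truncates the slow
  # phase, so the intercept-based fraction underestimates the 0.95 mixture
  expect_equal(fastFraction(fit), 0.7910, tolerance = 1e-3)
  expect_equal(halfLife(fit), 0.6113, tolerance = 1e-3)
})

test_that("well-separated phases recover the mixture fraction", {
  # slow pool effectively flat and fully resolved by the window:
  # the extrapolated intercepts give a clean fraction estimate
  tt <- seq(0, 16, by = 1)
  y <- log2(0.95 * 2^(-tt / 0.5) + 0.05 * 2^(-tt / 2000))
  fit <- segmentBiphasic(tt, y)
  expect_true(isBiphasic(fit))
  expect_lt(abs(fastFraction(fit) - 0.95), 0.03)
  expect_lt(fit@fast@slope, fit@slow@slope)
})

test_that("exactly piecewise-linear decay is recovered without bias", {
  # data that truly follow the two-segment model: both half-lives exact
  tt <- rep(c(0, 0.5, 1, 2, 3, 4, 6, 8), each = 2)
  y <- ifelse(tt <= 2, -tt / 0.5, -2 / 0.5 - (tt - 2) / 20)
  fit <- segmentBiphasic(tt, y)
  expect_true(isBiphasic(fit))
  expect_equal(halfLife(fit), 0.5, tolerance = 1e-9)
  expect_equal(halfLife(slowPhase(fit)), 20, tolerance = 1e-9)
})

test_that("chosen breakpoint matches exhaustive SSE minimization on random instances", {
  set.seed(42)
  n_biphasic <- 0
  for (i in 1:200) {
    k <- sample(4:8, 1)
    times <- rep(sort(sample(0:10, k)), each = sample(1:3, 1))
    hl_f <- runif(1, 0.3, 1.5); hl_s <- hl_f * runif(1, 3, 30)
    frac <- runif(1, 0.6, 0.98)
    y <- log2(frac * 2^(-times / hl_f) + (1 - frac) * 2^(-times / hl_s)) +
      rnorm(length(times), 0, 0.05)
    fit <- suppressWarnings(segmentBiphasic(times, y))
    if (isBiphasic(fit)) {
      n_biphasic <- n_biphasic + 1
      expect_identical(fit@breakpoint_index,
                       as.integer(brute_force_segments(times, y)$b))
    }
  }
  expect_gt(n_biphasic, 20)   # the property was actually exercised
})

test_that("estimateHalfLife pools replicates and requires the t = 0 anchor", {
  tab <- make_chase_table(1.5, noise_sd = 0, n_rep = 3)
  fit <- estimateHalfLife(tab, "s1", "yfp")
  expect_equal(halfLife(fit), 1.5, tolerance = 1e-9)
  df <- as.data.frame(tab)
  no_zero <- CtTable(df[df$time_min > 0, ])
  expect_error(estimateHalfLife(no_zero, "s1", "yfp"), "t = 0")
  expect_error(estimateHalfLife(tab, "nope", "yfp"), "no chase rows")
})

test_that("noisy half-life estimates recover truth within tolerance", {
  hits <- 0
  for (seed in 1:50) {
    tab <- make_chase_table(1.5, noise_sd = 0.1, seed = seed)
    est <- halfLife(estimateHalfLife(tab, "s1", "yfp"))
    if (abs(est - 1.5) / 1.5 <= 0.2) hits <- hits + 1
  }
  expect_gte(hits, 47)   # >= 94% of 50 seeds at the +-20% band
})

test_that("slope comparison is null on identical data and detects real differences", {
  set.seed(5)
  t <- rep(c(0, 1, 2, 4), each = 3)
  y <- -20 - t / 1.5 + rnorm(length(t), 0, 0.1)
  res <- compareDecaySlopes(t, y, t, y)
  expect_equal(res$difference, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1)
  # strong true difference: 1.5 vs 0.6 min half-lives
  pow <- 0
  for (seed in 1:40) {
    a <- make_chase_table(1.5, noise_sd = 0.1, seed = seed)
    b <- make_chase_table(0.6, noise_sd = 0.1, seed = seed + 1000,
                          strain = "s2")
    tab <- CtTable(rbind(as.data.frame(a), as.data.frame(b)))
    res <- compareHalfLives(tab, "yfp", "s1", "s2")
    if (res$p_value < 0.05) pow <- pow + 1
  }
  expect_gte(pow, 36)   # >= 90% power
})
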