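test_that("steady state matches the single-pool reduction and trivial limits", {
  ss <- steadyState(TwoPoolParams(alpha = 10, p = 1, k_t = 1, mu = 0.01))
  expect_equal(ss@m_translated, 10 / 1.01)
  expect_identical(ss@m_dark, 0)
  ss0 <- steadyState(TwoPoolParams(alpha = 0, p = 0.5, k_t = 1, mu = 0.01))
  expect_identical(poolAbundances(ss0)[1:2],
                   c(m_translated = 0, m_dark = 0))
  expect_error(steadyState(TwoPoolParams(alpha = 1, p = 1, k_t = 0, k_d = 0,
                                         mu = 0)), "diverges")
  # mu = 0: protein has no steady state
  expect_true(is.na(steadyState(TwoPoolParams(alpha = 1, p = 1, k_t = 1,
                                              mu = 0, beta = 1))@protein))
})

test_that("closed-form steady state agrees with numerical ODE integration", {
  skip_if_not_installed("deSolve")
  par <- TwoPoolParams(alpha = 10, p = 0.5, k_t = 0.5, k_d = 50, mu = 0.004,
                       beta = 2)
  rhs <- function(t, y, pm) {
    list(c(pm$p * pm$alpha - (pm$k_t + pm$mu) * y[1],
           (1 - pm$p) * pm$alpha - (pm$k_d + pm$mu) * y[2],
           pm$beta * y[1] - pm$mu * y[3]))
  }
  out <- deSolve::ode(c(0, 0, 0), seq(0, 5000, by = 50), rhs,
                      list(p = par@p, alpha = par@alpha, k_t = par@k_t,
                           k_d = par@k_d, mu = par@mu, beta = par@beta))
  final <- out[nrow(out), -1]
  ss <- steadyState(par)
  expect_equal(unname(final[1]), ss@m_translated, tolerance = 1e-6)
  expect_equal(unname(final[2]), ss@m_dark, tolerance = 1e-6)
  expect_equal(unname(final[3]), ss@protein, tolerance = 1e-4)
})

test_that("mass balance holds exactly at steady state", {
  set.seed(9)
  for (i in 1:50) {
    k_t <- runif(1, 0.05, 2)
    par <- TwoPoolParams(alpha = runif(1, 0.1, 100), p = runif(1),
                         k_t = k_t, k_d = k_t * runif(1, 1, 200),
                         mu = runif(1, 1e-4, 0.02))
    ss <- steadyState(par)
    flux <- (par@k_t + par@mu) * ss@m_translated +
            (par@k_d + par@mu) * ss@m_dark
    expect_equal(flux, par@alpha, tolerance = 1e-12)
  }
})

test_that("simulated chases are reproducible and noiseless curves are exact", {
  par <- TwoPoolParams(alpha = 10, p = 1, k_t = log(2) / 1.5)
  c1 <- simulateChase(par, ct_noise_sd = 0.1, seed = 99)
  c2 <- simulateChase(par, ct_noise_sd = 0.1, seed = 99)
  expect_identical(as.data.frame(ctTable(c1)), as.data.frame(ctTable(c2)))
  c3 <- simulateChase(par, ct_noise_sd = 0.1, seed = 100)
  expect_false(identical(as.data.frame(ctTable(c1))$ct,
                         as.data.frame(ctTable(c3))$ct))
  # p = 1, no noise: -ct exactly linear with slope -(k_t + mu)/ln2
  c0 <- simulateChase(par, ct_noise_sd = 0)
  df <- as.data.frame(ctTable(c0))
  slope <- coef(lm(-ct ~ time_min, df))[2]
  expect_equal(unname(slope), -(par@k_t + par@mu) / log(2), tolerance = 1e-12)
  expect_error(simulateChase(TwoPoolParams(alpha = 0, p = 1, k_t = 1)),
               "zero")
})

test_that("chase noise does not alter the recorded true abundances", {
  par <- TwoPoolParams(alpha = 5, p = 0.8, k_t = 0.3, k_d = 3)
  a <- simulateChase(par, ct_noise_sd = 0)
  b <- simulateChase(par, ct_noise_sd = 0.5, seed = 4)
  expect_identical(a@true_abundance, b@true_abundance)
  expect_true(all(diff(a@true_abundance) <= 0))
})

test_that("segmentation recovers the dark pool's steady-state abundance share", {
  # moderate separation so both phases are visible within the window
  par <- TwoPoolParams(alpha = 10, p = 0.5, k_t = 0.1, k_d = 1.5,
                       mu = 0.001)
  ss <- steadyState(par)
  dark_share <- ss@m_dark / (ss@m_dark + ss@m_translated)
  chase <- simulateChase(par, times = seq(0, 8, by = 0.25),
                         n_replicates = 1L, ct_noise_sd = 0)
  df <- as.data.frame(ctTable(chase))
  fit <- segmentBiphasic(df$time_min, -df$ct)
  expect_true(isBiphasic(fit))
  expect_lt(abs(fastFraction(fit) - dark_share), 0.02)
})

test_that("inferred production rate converges to p for a fast dark pool", {
  kt <- log(2) / 1.5
  mu <- log(2) / 180
  expect_equal(apparentProductionRate(
    TwoPoolParams(alpha = 10, p = 1, k_t = kt, mu = mu)), 1,
    tolerance = 0.02)
  expect_equal(apparentProductionRate(
    TwoPoolParams(alpha = 10, p = 0.5, k_t = kt, k_d = 100 * kt, mu = mu)),
    0.5, tolerance = 0.025)
  # indistinguishable pools: no bias at any p
  for (p in c(0.2, 0.6, 0.9))
    expect_equal(apparentProductionRate(
      TwoPoolParams(alpha = 10, p = p, k_t = kt, k_d = kt, mu = mu)), 1,
      tolerance = 0.02)
})

test_that("production-rate bias is monotone in dark-pool decay rate", {
  kt <- log(2) / 1.5
  for (p in c(0.3, 0.7)) {
    ratios <- vapply(c(1, 5, 25, 125, 625), function(r)
      apparentProductionRate(TwoPoolParams(alpha = 10, p = p, k_t = kt,
                                           k_d = r * kt,
                                           mu = log(2) / 180)),
      numeric(1))
    expect_true(all(diff(ratios) < 1e-9))
    expect_equal(ratios[1], 1, tolerance = 0.02)
    expect_equal(ratios[length(ratios)], p, tolerance = 0.025)
  }
})
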