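make_series <- function(t, fe2, dens = NULL, ...) {
  CultureSeries(time_days = t, acetate_mM = seq_along(t),
                fe2_total_mM = fe2,
                cell_density = if (is.null(dens)) numeric(0) else dens, ...)
}

test_that("window selection agrees with exhaustive enumeration", {
  set.seed(101)
  for (i in 1:25) {
    n <- sample(6:12, 1)
    t <- sort(sample(seq(0, 20, 0.5), n))
    dens <- 2e8 / (1 + 199 * exp(-runif(1, 0.4, 1.2) * t)) *
      exp(rnorm(n, 0, 0.1))
    s <- make_series(t, fe2 = rep(0, n), dens = dens)
    expect_equal(selectExponentialWindow(s), oracle_exp_window(t, dens))
  }
})

test_that("window selection handles the degenerate and minimal cases", {
  t <- c(0, 3, 6)
  s <- make_series(t, fe2 = c(0, 1, 2), dens = 1e6 * exp(0.8 * t))
  expect_equal(selectExponentialWindow(s), c(0, 6))   # only candidate
  s2 <- make_series(t, fe2 = c(0, 1, 2), dens = rep(5e7, 3))
  expect_error(selectExponentialWindow(s2), "constant")
  s3 <- make_series(c(0, 2), fe2 = c(0, 1), dens = c(1e6, 1e7))
  expect_error(selectExponentialWindow(s3), "at least 3")
})

test_that("a pure exponential over many points selects the full range", {
  t <- seq(0, 10, 2)
  s <- make_series(t, fe2 = rep(0, 6), dens = 1e6 * exp(0.5 * t))
  expect_equal(selectExponentialWindow(s), c(0, 10))
})

test_that("Fe(II) rate fits recover exact lines with full diagnostics", {
  t <- c(0, 2, 4, 6)
  est <- fe2ProductionRate(make_series(t, 0.5 * t), window = c(0, 6))
  expect_equal(rateSlope(est), 0.5)
  expect_equal(rSquared(est), 1)
  expect_equal(rateStderr(est), 0)
  expect_equal(nPoints(est), 4L)
  expect_equal(fitWindow(est), c(0, 6))

  flat <- fe2ProductionRate(make_series(t, rep(1.2, 4)), window = c(0, 6))
  expect_equal(rateSlope(flat), 0)
  expect_true(is.na(rSquared(flat)))

  expect_error(fe2ProductionRate(make_series(t, 0.5 * t), window = c(0, 2)),
               "at least 3")
})

test_that("rate stderr matches lm() on noisy data", {
  set.seed(5)
  t <- seq(0, 14, 2)
  fe2 <- 0.4 * t + rnorm(8, 0, 0.2)
  est <- fe2ProductionRate(make_series(t, fe2), window = c(0, 14))
  ref <- summary(lm(fe2 ~ t))$coefficients
  expect_equal(rateSlope(est), ref["t", "Estimate"])
  expect_equal(rateStderr(est), ref["t", "Std. Error"])
})

test_that("stationary accumulation averages the trailing observations", {
  s <- make_series(c(0, 2, 4, 6), c(0, 1, 2.85, 2.95))
  expect_equal(finalAccumulation(s), 2.9)
  expect_equal(finalAccumulation(s, k_last = 1), 2.95)
  expect_error(finalAccumulation(s, k_last = 0), ">= 1")
})

test_that("fraction reduced is a plain percentage with the right invariances", {
  expect_equal(fractionReduced(2.9, 9), 100 * 2.9 / 9)
  expect_equal(fractionReduced(0, 9), 0)
  expect_equal(fractionReduced(9, 9), 100)
  # monotone in fe2, invariant under joint rescaling
  v <- fractionReduced(c(1, 2, 2.5), 9)
  expect_true(all(diff(v) > 0))
  expect_equal(fractionReduced(2.9 * 3, 9 * 3), fractionReduced(2.9, 9))
  expect_error(fractionReduced(1, 0), "> 0")
})

test_that("sediment partitioning subtracts, clamps, and flags", {
  expect_equal(as.numeric(partitionSediment(9, 2.9)), 6.1)
  expect_equal(as.numeric(partitionSediment(5, 5)), 0)
  expect_warning(p <- partitionSediment(5, 5.2), "clamped")
  expect_equal(as.numeric(p), 0)
  expect_true(attr(p, "flagged"))
  # inside tolerance: clamped but not flagged
  expect_false(attr(partitionSediment(5, 5.04), "flagged"))
})

test_that("noiseless preset output returns the configured rate and plateau", {
  out <- generateCulture(cultureConfig("gt1-organo", noise_sd = 0), seed = 3)
  s <- out$treatment[[1]]
  est <- fe2ProductionRate(s)
  expect_equal(rateSlope(est), 0.47, tolerance = 1e-12)
  expect_equal(finalAccumulation(s), 2.9, tolerance = 1e-12)
  rep <- kineticsReport(out$treatment)
  expect_equal(nrow(rep), 3)
  expect_equal(rep$rate_mM_day, rep(0.47, 3))
  expect_equal(rep$pct_fe3_reduced, rep(100 * 2.9 / 9, 3))
})
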