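# brute-force oracle: dense grid over the decay rate with exact linear
# least squares for (a, c) at each candidate; independent of the
# package's profiled Brent search
gridFitOracle <- function(y, bGrid = seq(0.001, 1, by = 5e-4)) {
  i <- seq_along(y) - 1
  best <- NULL
  for (b in bGrid) {
    X <- cbind(exp(-b * i), 1)
    cf <- qr.coef(qr(X), y)
    rss <- sum((y - X %*% cf)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(a = unname(cf[1]), b = b, c = unname(cf[2]), rss = rss)
  }
  best
}

test_that("noiseless model parameters are recovered to 1e-6 relative", {
  y <- 50 * exp(-0.1 * (0:19)) + 70
  f <- fitExponential(y)
  expect_true(f@converged)
  expect_equal(f@a, 50, tolerance = 1e-6)
  expect_equal(f@b, 0.1, tolerance = 1e-6)
  expect_equal(f@c, 70, tolerance = 1e-6)
  expect_lt(f@rss, 1e-12)
})

test_that("fit is deterministic and needs at least 4 points", {
  y <- 50 * exp(-0.1 * (0:19)) + 70 + sin(0:19)
  f1 <- fitExponential(y)
  f2 <- fitExponential(y)
  expect_identical(c(f1@a, f1@b, f1@c, f1@rss),
                   c(f2@a, f2@b, f2@c, f2@rss))
  expect_error(fitExponential(c(3, 2, 1)), "at least 4")
  expect_error(fitExponential(c(1, 2, NA, 4)), "finite")
})

test_that("a constant series is flagged degenerate with rss ~ 0", {
  f <- fitExponential(rep(80, 10))
  expect_true(f@converged)
  expect_true(f@degenerate)
  expect_equal(f@a * exp(-f@b * (0:9)) + f@c, rep(80, 10),
               tolerance = 1e-9)
  expect_lt(f@rss, 1e-12)
  expect_match(f@warnings, "degenerate", all = FALSE)
})

test_that("a growing series converges with a not-a-decay warning", {
  y <- 50 * exp(0.05 * (0:19)) + 10
  f <- fitExponential(y)
  expect_true(f@converged)
  expect_lt(f@b, 0)
  expect_match(f@warnings, "not a decay", all = FALSE)
})

test_that("noisy recovery matches the brute-force grid oracle within 5%", {
  set.seed(314)
  y <- 50 * exp(-0.1 * (0:49)) + 70 + rnorm(50, sd = 0.5)
  f <- fitExponential(y)
  o <- gridFitOracle(y)
  expect_lte(f@rss, o$rss + 1e-9)  # profiled search at least as good
  expect_equal(f@a, 50, tolerance = 0.05)
  expect_equal(f@b, 0.1, tolerance = 0.05)
  expect_equal(f@c, 70, tolerance = 0.05)
  expect_equal(f@a, o$a, tolerance = 0.05)
  expect_equal(f@b, o$b, tolerance = 0.05)
  expect_equal(f@c, o$c, tolerance = 0.05)
})

test_that("two-pass correction flattens an exact-model series", {
  means <- 50 * exp(-0.1 * (0:19)) + 70
  stk <- constStack(means, Y = 5, X = 5)
  res <- correctExponential(stk)
  # pass 2 offset collapses to ~0 and corrected means sit at the
  # frame-0 subtracted mean
  expect_equal(fitParams(res)$pass2@c, 0, tolerance = 1e-4)
  expect_equal(meanSeries(res), rep(50, 20), tolerance = 1e-4)
  # frame 0 is changed only by the -c subtraction (factor exactly 1)
  expect_equal(as.numeric(frameReport(res)$ratio_or_lut_id)[1], 1)
  expect_equal(unname(frames(res)[1, 1, 1, 1]),
               120 - fitParams(res)$pass1@c, tolerance = 1e-6)
})

test_that("two runs on identical input are bit-identical", {
  stk <- simulateBleachedStack(tinyFixtureConfig())
  r1 <- correctExponential(stk)
  r2 <- correctExponential(stk)
  expect_identical(frames(r1), frames(r2))
  expect_identical(fitParams(r1)$pass2@b, fitParams(r2)$pass2@b)
})

test_that("single-frame fluctuations survive the correction", {
  # the fit sees an idealized decay; a one-frame spike must pass
  # through to the corrected series rather than being flattened
  means <- 50 * exp(-0.1 * (0:49)) + 70
  spiked <- means
  k <- 26  # frame index 25; +10% on the signal (above-background) part
  spiked[k] <- 70 + (means[k] - 70) * 1.1
  base <- correctExponential(constStack(means, Y = 5, X = 5))
  pert <- correctExponential(constStack(spiked, Y = 5, X = 5))
  mB <- meanSeries(base); mP <- meanSeries(pert)
  # the spiked frame carries its ~+10% excursion into the output
  expect_equal((mP[k] - mB[k]) / mB[k], 0.1, tolerance = 0.2)
  # all other frames move only through the slightly perturbed fit;
  # the relative effect grows as the subtracted signal approaches zero
  # (late frames), so the tight bound applies where signal is strong
  rel <- abs(mP - mB) / mB
  expect_lt(max(rel[1:33][-k]), 0.01)
  expect_lt(max(rel[-k]), 0.05)
  expect_lt(stats::median(rel[-k]), 0.01)
})

test_that("parameter recovery is unbiased over repeated noisy draws", {
  # sd = 1% of the amplitude; bias of each parameter under 2%
  set.seed(99)
  est <- replicate(60, {
    y <- 50 * exp(-0.1 * (0:29)) + 70 + rnorm(30, sd = 0.5)
    f <- fitExponential(y)
    c(f@a, f@b, f@c)
  })
  bias <- rowMeans(est) - c(50, 0.1, 70)
  expect_lt(abs(bias[1]) / 50, 0.02)
  expect_lt(abs(bias[2]) / 0.1, 0.02)
  expect_lt(abs(bias[3]) / 70, 0.02)
})

test_that("degenerate pass-2 leaves the stack unscaled with a warning", {
  stk <- constStack(rep(80, 6), Y = 4, X = 4)
  res <- correctExponential(stk)
  expect_match(res@warnings, "degenerate", all = FALSE)
  expect_equal(as.numeric(frameReport(res)$ratio_or_lut_id), rep(1, 6))
  # output equals input minus the fitted offset (the constant itself)
  expect_equal(meanSeries(res), rep(0, 6), tolerance = 1e-9)
})
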