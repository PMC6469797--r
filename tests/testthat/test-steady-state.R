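test_that("closed-form steady state matches direct evaluation of the model", {
  rel <- glu_relax()
  expect_equal(rel$A, sqrt(1.15 / 0.1175))
  expect_identical(mzss_fraction(rel, 0), 1)
  # frozen values from direct evaluation of 1 - AX/sqrt(1 + A^2 X^2)
  expect_equal(mzss_fraction(rel, 36), 0.287132, tolerance = 1e-5)
  expect_equal(mzss_fraction(rel, 12), 0.687639, tolerance = 1e-5)
  expect_equal(mzss_fraction(rel, 24), 0.446276, tolerance = 1e-5)
  expect_error(mzss_fraction(rel, 91), "flip angle")
  expect_error(mzss_fraction(rel, -1), "flip angle")
})

test_that("steady-state fraction decreases in flip angle and in A", {
  fas <- seq(0, 90, by = 5)
  for (A in c(0.5, 1, 3.13, 10)) {
    v <- mzss_fraction(A, fas)
    expect_true(all(diff(v) < 0))
    expect_true(all(v > 0 & v <= 1))
  }
  for (fa in c(10, 36, 80)) {
    v <- vapply(c(0.5, 1, 2, 5, 10), mzss_fraction, numeric(1), fa_deg = fa)
    expect_true(all(diff(v) < 0))
  }
})

test_that("ratio statistic is exactly linear in tan(FA/2)", {
  # Rzss(Mzss(A, fa)) == A tan(fa/2), the identity behind the regression
  for (A in seq(0.5, 10, length.out = 20)) {
    fa <- seq(1, 90, length.out = 25)
    r <- rzss_from_amplitudes(1, mzss_fraction(A, fa))
    expect_equal(r, A * tan(fa * pi / 360), tolerance = 1e-10)
  }
  expect_identical(rzss_from_amplitudes(1, 1), 0)
  # scale invariance in m0
  expect_equal(rzss_from_amplitudes(2, 2 * 0.2871),
               rzss_from_amplitudes(1, 0.2871), tolerance = 1e-12)
  # frozen: equals A*X for the Glu-like case at 36 degrees
  expect_equal(rzss_from_amplitudes(1, mzss_fraction(glu_relax(), 36)),
               1.0165, tolerance = 1e-4)
})

test_that("amplitudes above M0 are clipped with a warning, non-positive error", {
  expect_warning(r <- rzss_from_amplitudes(1, 1.01), "clipping")
  expect_true(r >= 0 && r < 1e-2)
  expect_error(rzss_from_amplitudes(1, 0), "positive")
  expect_error(rzss_from_amplitudes(1, -0.2), "positive")
})

test_that("water-suppression recovery correction round-trips", {
  rel <- glu_relax()
  mzss <- mzss_fraction(rel, 36)
  obs <- ws_recovery_observe(mzss, 1, 0.2, rel$t1)
  expect_equal(obs, 0.4009, tolerance = 1e-4)      # forward-simulated value
  expect_equal(correct_ws_recovery(obs, 1, 0.2, rel$t1), mzss,
               tolerance = 1e-12)
  expect_identical(correct_ws_recovery(0.37, 1, 0, rel$t1), 0.37)
  expect_equal(correct_ws_recovery(1, 1, 0.5, rel$t1), 1)  # equilibrium fixed
  expect_error(correct_ws_recovery(0.01, 1, 2, 0.1), "non-positive")
})

test_that("T2 follows from T1 and A with delta-method uncertainty", {
  expect_equal(t2_from_t1_A(1.15, sqrt(1.15 / 0.1175))[["t2"]], 0.1175)
  expect_equal(t2_from_t1_A(1, 1)[["t2"]], 1)
  out <- t2_from_t1_A(1.15, 3.1285, t1_se = 0.14, A_se = 0.02 * 3.1285)
  expect_equal(out[["se"]] / out[["t2"]],
               sqrt((0.14 / 1.15)^2 + (2 * 0.02)^2), tolerance = 1e-10)
  # numeric-resampling oracle for the propagation at small noise
  set.seed(42)
  t1s <- rnorm(2e5, 1.15, 0.14 / 20)
  As <- rnorm(2e5, 3.1285, 3.1285 * 0.02 / 20)
  emp <- sd(t1s / As^2) / mean(t1s / As^2)
  pred <- sqrt((0.14 / 20 / 1.15)^2 + (2 * 0.02 / 20)^2)
  expect_equal(emp, pred, tolerance = 0.02)
})

test_that("A is recovered exactly from noiseless closed-form amplitudes", {
  for (A in c(1, 3.1285, 7)) {
    fa <- c(0, 12, 24, 36)
    amp <- mzss_fraction(A, fa)
    est <- estimate_A(fa, amp)
    expect_equal(est[["A"]], A, tolerance = 1e-10)
    expect_lt(est[["se"]], 1e-10)
  }
  # hand-checkable case: slope 2, perfect line
  x <- c(0.1, 0.2, 0.3)
  fa <- 2 * atan(x) * 180 / pi
  mz <- 1 - (2 * x) / sqrt(1 + (2 * x)^2)
  est <- estimate_A(c(0, fa), c(1, mz))
  expect_equal(est[["A"]], 2, tolerance = 1e-12)
  expect_error(estimate_A(c(0, 0), c(1, 1)), "distinct")
  expect_error(estimate_A(0, 1), "length|>= 2")
})

test_that("A estimate is unbiased under amplitude noise (Monte Carlo)", {
  A <- 3.1285
  fa <- c(0, 12, 24, 36)
  clean <- mzss_fraction(A, fa)
  set.seed(11)
  ests <- replicate(100, {
    amp <- pmin(clean + rnorm(4, 0, 0.005), 0.9999)
    amp[1] <- 1
    estimate_A(fa, amp)[["A"]]
  })
  se_mean <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - A), 3 * se_mean + 0.003)
})
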