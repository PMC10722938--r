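# Mono-exponential fitting: log-linear oracle and Levenberg-Marquardt.

test_that("both estimators are exact on noiseless decays", {
  withr::with_seed(1, {
    S0 <- runif(200, 20, 500)
    Tv <- runif(200, 5, 150)
  })
  es <- decay_series(S0, Tv)
  ll <- loglinear_fit(es)
  lm <- fit_monoexponential(es)
  expect_lt(max(abs(ll$time_ms[, 1, 1] - Tv) / Tv), 1e-6)
  expect_lt(max(abs(lm$time_ms[, 1, 1] - Tv) / Tv), 1e-6)
  expect_lt(max(abs(ll$s0[, 1, 1] - S0) / S0), 1e-6)
  expect_lt(max(abs(lm$time_ms - ll$time_ms) / ll$time_ms), 1e-8)
  expect_true(all(lm$r_squared[, 1, 1] > 1 - 1e-9))
})

test_that("a 3-echo subset still recovers T exactly", {
  es <- decay_series(100, 40, echo_times = c(0, 10, 40))
  ll <- loglinear_fit(es)
  expect_equal(ll$time_ms[1, 1, 1], 40, tolerance = 1e-9)
  expect_equal(ll$s0[1, 1, 1], 100, tolerance = 1e-9)
})

test_that("flat (non-decaying) signals are flagged unfitted, not errors", {
  dat <- array(100, c(2, 1, 1, 4))
  es <- echo_series(dat, c(0, 10, 40, 80))
  ll <- loglinear_fit(es)
  expect_false(any(ll$converged))
  expect_true(all(is.na(ll$time_ms)))
})

test_that("non-positive signals in the mask flag voxels, not exceptions", {
  dat <- array(0, c(2, 1, 1, 4))
  dat[1, 1, 1, ] <- 100 * exp(-c(0, 10, 40, 80) / 40)
  dat[2, 1, 1, ] <- c(100, -1, 30, 10)
  es <- echo_series(dat, c(0, 10, 40, 80))
  ll <- loglinear_fit(es)
  expect_true(ll$converged[1, 1, 1])
  expect_false(ll$converged[2, 1, 1])
})

test_that("empty mask errors; bad bounds error", {
  es <- decay_series(100, 40)
  expect_error(fit_monoexponential(es, mask = array(FALSE, c(1, 1, 1))), "empty mask")
  expect_error(fit_monoexponential(es, bounds = c(5, 2)), "bounds")
})

test_that("scale equivariance: c * S leaves T unchanged, scales S0", {
  withr::with_seed(2, { S0 <- runif(50, 50, 150); Tv <- runif(50, 10, 100) })
  es1 <- decay_series(S0, Tv)
  es2 <- decay_series(S0 * 7.5, Tv)
  m1 <- fit_monoexponential(es1)
  m2 <- fit_monoexponential(es2)
  expect_lt(max(abs(m2$time_ms - m1$time_ms) / m1$time_ms), 1e-8)
  expect_lt(max(abs(m2$s0 - 7.5 * m1$s0) / m2$s0), 1e-8)
})

test_that("doubling echo times doubles the fitted T exactly (noiseless)", {
  es1 <- decay_series(100, 40, echo_times = c(0, 10, 40, 80))
  es2 <- decay_series(100, 80, echo_times = c(0, 20, 80, 160))
  m1 <- fit_monoexponential(es1)
  m2 <- fit_monoexponential(es2)
  expect_equal(m2$time_ms[1, 1, 1], 2 * m1$time_ms[1, 1, 1], tolerance = 1e-9)
})

test_that("RMSE is non-increasing as noise decreases", {
  t <- c(0, 10, 40, 80)
  V <- 3000
  rmse <- sapply(c(4, 2, 1), function(sdn) {
    dat <- array(rep(100 * exp(-t / 30), each = V), c(V, 1, 1, 4)) +
      withr::with_seed(42, array(rnorm(V * 4, 0, sdn), c(V, 1, 1, 4)))
    m <- fit_monoexponential(echo_series(dat, t))
    sqrt(mean((m$time_ms[, 1, 1] - 30)^2))
  })
  expect_true(all(diff(rmse) <= 0))
})

test_that("fit_quality_mask enforces convergence, R^2 and open bounds", {
  withr::with_seed(3, { S0 <- runif(100, 50, 150); Tv <- runif(100, 10, 100) })
  es <- decay_series(S0, Tv)
  m <- fit_monoexponential(es)
  # min_r_squared = 0 on a noiseless fit excludes nothing
  expect_identical(fit_quality_mask(m, min_r_squared = 0), array(m$mask, dim(m$mask)))
  # a voxel pushed to the T_max bound is excluded
  m2 <- m
  m2$time_ms[1, 1, 1] <- m$bounds[2]
  qm <- fit_quality_mask(m2, min_r_squared = 0)
  expect_false(qm[1, 1, 1])
  expect_true(all(qm[2:100, 1, 1]))
})

test_that("corrupted non-decaying voxels are excluded at the corrupted rate", {
  t <- c(0, 10, 40, 80)
  V <- 4000
  withr::with_seed(9, {
    dat <- array(rep(100 * exp(-t / 40), each = V), c(V, 1, 1, 4)) +
      array(rnorm(V * 4, 0, 2), c(V, 1, 1, 4))
    bad <- sample(V, round(0.05 * V))
    for (e in 1:4) dat[cbind(bad, 1, 1, e)] <- rnorm(length(bad), 100, 2)
  })
  m <- fit_monoexponential(echo_series(dat, t))
  qm <- fit_quality_mask(m, min_r_squared = 0.8)
  excl <- 1 - mean(qm)
  # binomial 99.9% interval around 5%
  expect_lt(abs(excl - 0.05), 3.3 * sqrt(0.05 * 0.95 / V) + 0.002)
})
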