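test_that("generators are bitwise deterministic given a seed", {
  spec <- trend_spec("arima021", n = 50)
  expect_identical(simulate_trend(spec, seed = 4), simulate_trend(spec, seed = 4))
  p1 <- simulate_pair(rep(0, 30), rep(0, 30), seed = 5)
  p2 <- simulate_pair(rep(0, 30), rep(0, 30), seed = 5)
  expect_identical(p1, p2)
  s1 <- simulate_session(session_spec(3, n_stimuli = 4, n_blocks = 5), seed = 6)
  s2 <- simulate_session(session_spec(3, n_stimuli = 4, n_blocks = 5), seed = 6)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$stimulus, s2$stimulus)
})

test_that("trend families realize their closed forms", {
  expect_equal(simulate_trend(trend_spec("constant", n = 9, level = 2)),
               rep(2, 9))
  expect_equal(simulate_trend(trend_spec("linear", n = 5, intercept = 1,
                                         slope = 2)),
               c(1, 3, 5, 7, 9))
  expect_equal(simulate_trend(trend_spec("stepwise", n = 6,
                                         change_points = 4L,
                                         levels = c(0, 10))),
               c(0, 0, 0, 10, 10, 10))
  sine <- simulate_trend(trend_spec("sinusoid", n = 100, amplitude = 1.5,
                                    n_cycles = 7))
  expect_equal(sine, 1.5 * sin(2 * pi * 7 * (0:99) / 100))
  expect_lt(abs(mean(sine)), 1e-12)
})

test_that("the drifting baseline is a twice-integrated MA(1) process", {
  # theta = 0: second differences recover iid innovations
  spec0 <- trend_spec("arima021", n = 2000, theta = 0, innovation_sd = 1)
  tr0 <- simulate_trend(spec0, seed = 10)
  d2 <- diff(tr0, differences = 2)
  expect_equal(sd(d2), 1, tolerance = 0.06)
  expect_lt(abs(cor(d2[-1], d2[-length(d2)])), 0.06)

  # theta = 0.6: second differences have the MA(1) lag-1 autocorrelation
  spec6 <- trend_spec("arima021", n = 2000, theta = 0.6, innovation_sd = 1)
  d2b <- diff(simulate_trend(spec6, seed = 11), differences = 2)
  expect_lt(abs(cor(d2b[-1], d2b[-length(d2b)]) - 0.6 / (1 + 0.36)),
            0.08)
})

test_that("pair noise reproduces the requested correlation at large N", {
  p <- simulate_pair(rep(0, 1e5), rep(0, 1e5), noise_spec(rho = 0.3),
                     seed = 12)
  expect_lt(abs(cor(p$x, p$y) - 0.3), 0.012)
  p0 <- simulate_pair(rep(0, 1e5), rep(0, 1e5), noise_spec(rho = 0),
                      seed = 13)
  expect_lt(abs(cor(p0$x, p0$y)), 0.01)
  expect_error(noise_spec(rho = 1.2), "rho")
  expect_error(noise_spec(s11 = -1), "positive")
})

test_that("populations share the trend and only neurons 1-2 correlate", {
  set.seed(14)
  tr <- simulate_trend(trend_spec("sinusoid", n = 100, amplitude = 3))
  X <- simulate_population(5, tr, noise_spec(rho = 0.5))
  expect_equal(dim(X), c(100L, 5L))
  expect_gt(cor(X[, 4], tr), 0.8)
  # at the default slow-drift amplitude, pairs excluding neuron 2 are null
  tr_slow <- simulate_trend(trend_spec("sinusoid", n = 100))
  r13 <- replicate(50, {
    X <- simulate_population(4, tr_slow, noise_spec(rho = 0.5))
    short_term_correlation(X[, 1], X[, 3])
  })
  expect_lt(abs(mean(r13)), 0.07)
})

test_that("the drift-bias scenario shows the second-order variance bias", {
  db0 <- simulate_drift_bias_pair(5, 0, 1, 5e4, seed = 15)
  expect_lt(abs(local_pair_covariances(db0$x, db0$y)$s11 - 1), 0.02)
  db <- simulate_drift_bias_pair(5, 0.5, 1, 5e4, seed = 16)
  expect_lt(abs(local_pair_covariances(db$x, db$y)$s11 - 1.5), 0.03)
  # quadratic growth: fit E[s11] - sigma^2 ~ beta * eps^2, expect beta = 2
  eps_grid <- c(0.2, 0.4, 0.6, 0.8)
  bias <- vapply(seq_along(eps_grid), function(i) {
    d <- simulate_drift_bias_pair(0, eps_grid[i], 1, 5e4, seed = 20 + i)
    local_pair_covariances(d$x, d$y)$s11 - 1
  }, numeric(1))
  beta <- coef(lm(bias ~ 0 + I(eps_grid^2)))[[1]]
  expect_lt(abs(beta - 2), 0.1)
})

test_that("per-stimulus subseries keep the estimator unbiased for every trend family", {
  set.seed(17)
  specs <- list(
    constant = trend_spec("constant", n = 100),
    linear   = trend_spec("linear", n = 100, slope = 0.05),
    stepwise = trend_spec("stepwise", n = 100, change_points = 51L,
                          levels = c(0, 2)),
    sinusoid = trend_spec("sinusoid", n = 100),
    arima021 = trend_spec("arima021", n = 100))
  for (nm in names(specs)) {
    rhos <- replicate(400, {
      tx <- simulate_trend(specs[[nm]])
      ty <- if (nm %in% c("constant", "linear", "stepwise", "sinusoid")) {
        tx  # shared trend
      } else {
        simulate_trend(specs[[nm]])  # independent drifts
      }
      p <- simulate_pair(tx, ty, noise_spec(rho = 0.3))
      short_term_correlation(p$x, p$y)
    })
    expect_lt(abs(mean(rhos) - 0.3), 0.03,
              label = sprintf("mean rho bias under %s trend", nm))
  }
})

test_that("simulated sessions respect the block design and count model", {
  sess <- simulate_session(session_spec(4), seed = 18)
  expect_true(check_block_design(sess))
  expect_equal(as.integer(table(sess$stimulus)), rep(40L, 16))
  expect_true(all(sess$duration >= 1 & sess$duration <= 1.7))
  expect_true(all(sess$counts >= 0))
  expect_identical(storage.mode(sess$counts), "integer")

  # strong linear drift makes every neuron nonstationary
  drift <- trend_spec("linear", n = 640, slope = 0.02)
  sessd <- simulate_session(session_spec(4, drift = drift), seed = 19)
  expect_length(select_neurons(sessd, "stationary"), 0L)
})
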