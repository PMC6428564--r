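make_rt <- function(n_neurons = 4, seed = 1, ...) {
  to_rates(simulate_session(session_spec(n_neurons, ...), seed = seed))
}

test_that("train/test splits follow the four schemes", {
  rt <- make_rt(seed = 21)
  eo <- split_by_scheme(rt, "even_odd")
  expect_length(eo$train, 16 * 20)
  expect_length(eo$test, 16 * 20)
  expect_length(intersect(eo$train, eo$test), 0L)

  fl <- split_by_scheme(rt, "former_latter")
  expect_length(intersect(fl$train, fl$test), 0L)
  # former trials precede latter trials within every stimulus
  for (s in unique(rt$stimulus)[1:3]) {
    tf <- rt$trial_index[fl$train[rt$stimulus[fl$train] == s]]
    tl <- rt$trial_index[fl$test[rt$stimulus[fl$test] == s]]
    expect_lt(max(tf), min(tl))
  }

  ff <- split_by_scheme(rt, "former_former")
  expect_true(ff$loo)
  expect_identical(sort(ff$train), sort(fl$train))

  fd <- split_by_scheme(rt, "former_latter_detrended")
  expect_true(fd$detrend)

  bad <- rt
  keep <- bad$stimulus != bad$stimulus[1] | seq_along(bad$stimulus) > 100
  bad$rates <- bad$rates[keep, , drop = FALSE]
  bad$stimulus <- bad$stimulus[keep]
  bad$duration <- bad$duration[keep]
  bad$trial_index <- bad$trial_index[keep]
  expect_error(split_by_scheme(bad, "even_odd"), "even number")
})

test_that("period-mean detrending centres each period idempotently", {
  set.seed(22)
  tr <- matrix(rnorm(60, mean = 5), 20)
  te <- matrix(rnorm(60, mean = 9), 20)
  d <- detrend_by_period_mean(tr, te)
  expect_equal(colMeans(d$train), rep(0, 3))
  expect_equal(colMeans(d$test), rep(0, 3))
  d2 <- detrend_by_period_mean(d$train, d$test)
  expect_equal(d2$train, d$train)
  expect_equal(d2$test, d$test)
})

test_that("the pooled-covariance LDA classifies and matches MASS::lda", {
  # two well-separated point classes
  tr_x <- rbind(matrix(0, 10, 2), matrix(10, 10, 2))
  tr_y <- rep(c("a", "b"), each = 10)
  res <- lda_decode(tr_x + rnorm(40, sd = 0.01), tr_y,
                    rbind(c(0, 0), c(10, 10)), c("a", "b"))
  expect_equal(res$success_rate, 1)

  # agreement with the reference implementation on well-conditioned data
  set.seed(23)
  n <- 60
  X <- rbind(MASS::mvrnorm(n, c(0, 0, 0), diag(3)),
             MASS::mvrnorm(n, c(2, 0, 1), diag(3)),
             MASS::mvrnorm(n, c(0, 2, -1), diag(3)))
  y <- rep(c("a", "b", "c"), each = n)
  Xt <- MASS::mvrnorm(90, c(1, 1, 0), diag(3))
  ours <- lda_decode(X, y, Xt, rep("a", 90), ridge = 0)$predicted
  ref <- as.character(predict(MASS::lda(X, grouping = y), Xt)$class)
  expect_identical(ours, ref)

  # singular pooled covariance needs ridge
  Xs <- cbind(rnorm(20), 0)
  ys <- rep(c("a", "b"), 10)
  expect_error(lda_decode(Xs, ys, Xs, ys, ridge = 0), "ridge")
  expect_s3_class(lda_decode(Xs, ys, Xs, ys, ridge = 1e-6),
                  "classification_result")

  # no tuning signal decodes at chance
  set.seed(24)
  rates <- replicate(30, {
    Xn <- matrix(rnorm(320), 160)
    yn <- rep(letters[1:16], 10)
    lda_decode(Xn[1:80, ], yn[1:80], Xn[81:160, ], yn[81:160])$success_rate
  })
  expect_lt(abs(mean(rates) - 1 / 16), 0.02)
})

test_that("decoding succeeds with strong tuning and degrades informatively", {
  sess <- simulate_session(session_spec(8), seed = 25)
  ff <- decode_session(sess, "former_former")
  expect_gt(ff$success_rate, 0.5)
  expect_equal(ff$n_test, 320L)
})

test_that("trial shuffling preserves marginals and removes correlations", {
  rt <- make_rt(n_neurons = 3, seed = 26, pair_rho = 0.5)
  sh <- trial_shuffle(rt, seed = 27)
  for (s in unique(rt$stimulus)) {
    idx <- which(rt$stimulus == s)
    for (j in 1:3) {
      expect_equal(sort(sh$rates[idx, j]), sort(rt$rates[idx, j]))
    }
  }
  expect_identical(trial_shuffle(rt, seed = 27)$rates, sh$rates)

  rho_post <- vapply(unique(rt$stimulus), function(s) {
    sub <- select_stimulus(sh, s)
    short_term_correlation(sub[, 1], sub[, 2])
  }, numeric(1))
  rho_pre <- vapply(unique(rt$stimulus), function(s) {
    sub <- select_stimulus(rt, s)
    short_term_correlation(sub[, 1], sub[, 2])
  }, numeric(1))
  expect_gt(mean(rho_pre), 0.25)
  expect_lt(abs(mean(rho_post)), 0.12)
})

test_that("neuron selection removes drifting and correlated neurons", {
  drift <- list(trend_spec("linear", n = 640, slope = 0.02),
                trend_spec("constant", n = 640),
                trend_spec("constant", n = 640))
  sess <- simulate_session(session_spec(3, drift = drift), seed = 28)
  kept <- select_neurons(sess, "stationary")
  expect_false(1L %in% kept)
  expect_true(all(c(2L, 3L) %in% kept))

  sess2 <- simulate_session(session_spec(3, pair_rho = 0.8), seed = 29)
  cfg <- run_config(seed = 29, monte_carlo_reps = 5e4)
  kept2 <- select_neurons(sess2, "no_short_term_pair", cfg)
  expect_false(any(c(1L, 2L) %in% kept2))
  expect_true(3L %in% kept2)
})

test_that("tuning-curve PCA reflects between-half baseline shifts", {
  rt <- make_rt(n_neurons = 5, seed = 30)
  # force identical halves: copy each stimulus's former trials onto latter
  for (s in unique(rt$stimulus)) {
    idx <- which(rt$stimulus == s)
    idx <- idx[order(rt$trial_index[idx])]
    h <- length(idx) %/% 2
    rt$rates[idx[(h + 1):(2 * h)], ] <- rt$rates[idx[1:h], ]
  }
  pc <- tuning_curve_pca(rt)
  former <- pc[pc$half == "former", c("pc1", "pc2")]
  latter <- pc[pc$half == "latter", c("pc1", "pc2")]
  expect_equal(unname(as.matrix(latter)), unname(as.matrix(former)))
  rot <- attr(pc, "rotation")
  expect_equal(unname(crossprod(rot)), diag(2), tolerance = 1e-10)

  # identical additive offset displaces all neurons identically
  rt2 <- make_rt(n_neurons = 5, seed = 30)
  for (s in unique(rt2$stimulus)) {
    idx <- which(rt2$stimulus == s)
    idx <- idx[order(rt2$trial_index[idx])]
    h <- length(idx) %/% 2
    rt2$rates[idx[(h + 1):(2 * h)], ] <- rt2$rates[idx[1:h], ] + 4
  }
  pc2 <- tuning_curve_pca(rt2)
  disp <- as.matrix(pc2[pc2$half == "latter", c("pc1", "pc2")]) -
    as.matrix(pc2[pc2$half == "former", c("pc1", "pc2")])
  expect_lt(max(apply(disp, 2, sd)), 1e-10)
  expect_gt(sqrt(sum(colMeans(disp)^2)), 0.1)
})

test_that("paired comparisons handle matched and degenerate inputs", {
  a <- c(0.5, 0.6, 0.7)
  res <- paired_rate_comparison(a, a)
  expect_equal(res$t, 0)
  expect_equal(res$p_value, 1)

  set.seed(31)
  b <- a + 0.1 + rnorm(3, sd = 1e-4)
  expect_lt(paired_rate_comparison(b, a)$p_value, 0.01)
  expect_equal(paired_rate_comparison(b, a)$t,
               -paired_rate_comparison(a, b)$t, tolerance = 1e-12)
  expect_error(paired_rate_comparison(a, a[1:2]), "matched")
})
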