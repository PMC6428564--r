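#' Monte-Carlo null distribution of the short-term correlation
#'
#' Draws `reps` independent pairs of white standard-Gaussian series of
#' length `n_trials`, applies [short_term_correlation()] to each, and
#' stores the sorted estimates. Because the estimator is location/scale
#' invariant, this single distribution is the exact finite-sample null of
#' "no short-term correlation" for Gaussian activities of any mean and
#' variance; for small true correlations its spread follows the variance
#' bound \eqn{\Sigma_{11}\Sigma_{22} + \Sigma_{12}\Sigma_{21}} per pair,
#' i.e. SD \eqn{\approx \sqrt{2/N}} (about 0.224 at N = 40).
#'
#' @param n_trials series length the null refers to; rounded down to even
#'   with a warning if odd.
#' @param reps number of Monte-Carlo replicates (default 1e6 for full
#'   accuracy; 1e4-1e5 suffices for exploration).
#' @param seed integer seed; same (n_trials, reps, seed) always yields the
#'   same distribution.
#' @param cache_dir optional directory; when given, the sorted samples are
#'   persisted to / loaded from a plain-text file (one header line, then
#'   one value per line) keyed by (n_trials, reps, seed).
#' @return object of class `null_distribution`: list with `n_trials`,
#'   `reps`, `seed` and sorted `samples`.
#' @export
build_null_distribution <- function(n_trials, reps = 1e6, seed = 1L,
                                    cache_dir = NULL) {
  n_trials <- as.integer(n_trials)
  if (n_trials < 2L) stop("n_trials must be >= 2", call. = FALSE)
  if (n_trials %% 2L == 1L) {
    warning("odd n_trials; rounding down to even")
    n_trials <- n_trials - 1L
  }
  reps <- as.integer(reps)
  if (!is.null(cache_dir)) {
    cache_file <- file.path(cache_dir,
                            sprintf("null_n%d_r%d_s%d.txt",
                                    n_trials, reps, as.integer(seed)))
    if (file.exists(cache_file)) {
      samples <- scan(cache_file, skip = 1L, quiet = TRUE)
      return(structure(list(n_trials = n_trials, reps = reps,
                            seed = as.integer(seed), samples = samples),
                       class = "null_distribution"))
    }
  }
  samples <- with_seed_(seed, {
    chunk <- 50000L
    out <- numeric(reps)
    done <- 0L
    while (done < reps) {
      m <- min(chunk, reps - done)
      X <- matrix(stats::rnorm(m * n_trials), nrow = m)
      Y <- matrix(stats::rnorm(m * n_trials), nrow = m)
      out[done + seq_len(m)] <- rho_hat_rows(X, Y)
      done <- done + m
    }
    out
  })
  samples <- sort(samples)
  if (!is.null(cache_dir)) {
    dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
    writeLines(c(sprintf("n_trials=%d reps=%d seed=%d",
                         n_trials, reps, as.integer(seed)),
                 sprintf("%.17g", samples)),
               cache_file)
  }
  structure(list(n_trials = n_trials, reps = reps,
                 seed = as.integer(seed), samples = samples),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("<null_distribution> n_trials=%d reps=%d sd=%.4f\n",
              x$n_trials, x$reps, stats::sd(x$samples)))
  invisible(x)
}

# Two-sided empirical p values for statistics `r` against sorted null
# samples, midpoint tie handling, floored at 2/reps.
empirical_p <- function(r, null) {
  s <- null$samples
  reps <- length(s)
  n_le <- findInterval(r, s)
  n_lt <- findInterval(r, s, left.open = TRUE)
  F_hat <- (n_lt + 0.5 * (n_le - n_lt)) / reps
  p <- 2 * pmin(F_hat, 1 - F_hat)
  pmin(pmax(p, 2 / reps), 1)
}

#' Monte-Carlo significance test for a short-term correlation
#'
#' Computes the short-term correlation of the pair and its two-sided
#' p value as the percentile of the estimate within the Monte-Carlo null
#' distribution (doubled one-tail empirical CDF with midpoint tie
#' handling, floored at `2/reps`). An estimate in the extreme tails
#' (classically the top 2.5% on either side) indicates a genuine
#' simultaneous noise correlation. Alternatively, `method = "normal"`
#' uses the asymptotic-normal approximation with the theoretical null
#' SD \eqn{\sqrt{2/N}}; it is faster but less accurate at small N and is
#' not the default.
#'
#' @inheritParams local_pair_covariances
#' @param null a [build_null_distribution()] object whose `n_trials`
#'   matches the usable (even) length of the pair.
#' @param alpha significance level for the `significant` flag.
#' @param method `"monte_carlo"` (default) or `"normal"`.
#' @return object of class `test_result`: list with `statistic`,
#'   `p_value`, `significant`, `method`. All `NA` when the estimate is
#'   undefined.
#' @export
short_term_test <- function(x, y, null, alpha = 0.01,
                            method = c("monte_carlo", "normal")) {
  method <- match.arg(method)
  n_use <- length(x) - length(x) %% 2L
  rho <- suppressWarnings(short_term_correlation(x, y))
  if (is.na(rho)) {
    return(structure(list(statistic = NA_real_, p_value = NA_real_,
                          significant = NA, method = "short_term_mc"),
                     class = "test_result"))
  }
  if (method == "monte_carlo") {
    if (null$n_trials != n_use) {
      stop(sprintf("null distribution is for n_trials=%d but pair has %d usable trials",
                   null$n_trials, n_use), call. = FALSE)
    }
    p <- empirical_p(rho, null)
  } else {
    p <- 2 * stats::pnorm(-abs(rho) / sqrt(2 / n_use))
  }
  structure(list(statistic = rho, p_value = p,
                 significant = p < alpha, method = "short_term_mc"),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s: statistic=%.4g p=%.4g significant=%s\n",
              x$method, x$statistic, x$p_value, x$significant))
  invisible(x)
}

#' Trial-shift control for a pair
#'
#' Advances one series by `shift` trials (truncating the non-overlapping
#' ends), destroying any simultaneous correlation while preserving each
#' series' drift. Because the estimator consumes trials in pairs, the
#' shift must be even (the "one-time-shifted" control is a two-trial
#' shift). Test p values on shifted pairs must be uniform — the central
#' robustness check.
#'
#' @inheritParams local_pair_covariances
#' @param shift even nonnegative trial shift, default 2.
#' @return list with shifted, equal-length `x` and `y`.
#' @export
shift_control <- function(x, y, shift = 2L) {
  shift <- as.integer(shift)
  n <- length(x)
  if (shift %% 2L != 0L) stop("shift must be even for the pairwise estimator",
                              call. = FALSE)
  if (shift < 0L || shift >= n) stop("shift must be in [0, length(x))",
                                     call. = FALSE)
  if (n - shift < 2L) stop("overlap after shifting is too short",
                           call. = FALSE)
  list(x = x[seq_len(n - shift)], y = y[seq_len(n - shift) + shift])
}

#' Block averages of a per-trial series
#'
#' Averages consecutive blocks of `block_size` trials. With the reference
#' block design (each block of 16 trials presents all 16 stimuli once)
#' this removes the stimulus contribution from a neuron's session-long
#' series, reducing 640 trials to 40 block means on which the
#' nonstationarity test operates. A trailing partial block is dropped
#' with a warning.
#'
#' @param series numeric per-trial series.
#' @param block_size trials per block, default 16.
#' @return numeric vector of block means.
#' @export
block_average <- function(series, block_size = 16L) {
  block_size <- as.integer(block_size)
  if (block_size < 1L) stop("block_size must be >= 1", call. = FALSE)
  n <- length(series)
  n_blocks <- n %/% block_size
  if (n_blocks * block_size < n) {
    warning("dropping trailing partial block")
  }
  if (n_blocks == 0L) stop("series shorter than one block", call. = FALSE)
  colMeans(matrix(series[seq_len(n_blocks * block_size)],
                  nrow = block_size))
}

#' Serial-correlation test for nonstationarity
#'
#' Tests the randomness of a series against slow drift using the
#' non-circular lag-1 serial correlation of the mean-centered series,
#' \eqn{r_1 = \sum (x_t-\bar x)(x_{t+1}-\bar x) / \sum (x_t-\bar x)^2},
#' referred to a Gaussian approximation of its null distribution with
#' mean \eqn{-1/n} and variance \eqn{(n-2)^2/(n^2(n-1))}. A drifting
#' baseline produces positive serial correlation in the block-averaged
#' series; the test's validity criterion is that its p values are uniform
#' for white Gaussian noise, which this normalization satisfies.
#'
#' @param series numeric series, length >= 10, non-constant.
#' @param alpha significance level, default 0.01 (used uncorrected, so
#'   that suspicious neurons land conservatively in the nonstationary
#'   pool).
#' @return a `test_result` with method `"serial_correlation"`.
#' @export
serial_correlation_test <- function(series, alpha = 0.01) {
  series <- as.numeric(series)
  n <- length(series)
  if (n < 10L) stop("series must have length >= 10", call. = FALSE)
  if (stats::sd(series) == 0) {
    return(structure(list(statistic = NA_real_, p_value = NA_real_,
                          significant = NA, method = "serial_correlation"),
                     class = "test_result"))
  }
  xc <- series - mean(series)
  r1 <- sum(xc[-n] * xc[-1L]) / sum(xc^2)
  z <- (r1 + 1 / n) / sqrt((n - 2)^2 / (n^2 * (n - 1)))
  p <- 2 * stats::pnorm(-abs(z))
  structure(list(statistic = r1, p_value = p,
                 significant = p < alpha, method = "serial_correlation"),
            class = "test_result")
}

#' Bonferroni-corrected pairwise significance level
#'
#' The session-wide level for the pairwise short-term test:
#' `base_alpha / (n_stimuli * n_neurons * (n_neurons - 1) / 2)`, dividing
#' by the number of stimulus-by-pair tests in a session.
#'
#' @param n_neurons neurons in the session (>= 2).
#' @param n_stimuli stimuli per session, default 16.
#' @param base_alpha uncorrected level, default 0.01.
#' @return numeric scalar level.
#' @export
bonferroni_level <- function(n_neurons, n_stimuli = 16L, base_alpha = 0.01) {
  if (n_neurons < 2L) stop("need at least 2 neurons", call. = FALSE)
  base_alpha / (n_stimuli * n_neurons * (n_neurons - 1) / 2)
}

#' Classify neuron pairs by stationarity and short-term significance
#'
#' Per neuron: nonstationary iff the serial-correlation test on the
#' block-averaged session-long rate series is significant at
#' `config$alpha_nonstationarity` (uncorrected). Per pair and stimulus:
#' short-term correlation tested against the Monte-Carlo null at the
#' Bonferroni level for the session. Pairs are labelled `s-s`, `s-n` or
#' `n-n` by their members' stationarity — the table behind the p-value
#' histograms stratified by pair type.
#'
#' @param session a `session_data`.
#' @param config a [run_config()].
#' @param null optional pre-built [build_null_distribution()] for the
#'   per-stimulus trial count; built from the config otherwise.
#' @return data.frame with one row per stimulus x pair: `stimulus`,
#'   `neuron_i`, `neuron_j`, `rho`, `p_value`, `significant` (at the
#'   Bonferroni level), `pair_class`.
#' @export
classify_pairs <- function(session, config = run_config(), null = NULL) {
  validate_session(session)
  rt <- to_rates(session)
  n_neurons <- ncol(rt$rates)
  stimuli <- sort(unique(rt$stimulus))
  # per-neuron stationarity from the block-averaged full-session series
  stationary <- vapply(seq_len(n_neurons), function(i) {
    blocks <- block_average(rt$rates[, i], config$block_size)
    res <- serial_correlation_test(blocks, config$alpha_nonstationarity)
    if (is.na(res$significant)) NA else !res$significant
  }, logical(1))
  n_per_stim <- min(table(rt$stimulus))
  n_use <- n_per_stim - n_per_stim %% 2L
  if (is.null(null)) {
    null <- build_null_distribution(n_use, reps = config$monte_carlo_reps,
                                    seed = child_seed(config$seed, "null"))
  }
  level <- bonferroni_level(n_neurons, length(stimuli),
                            config$alpha_pairwise_base)
  pairs <- utils::combn(n_neurons, 2L)
  rows <- vector("list", length(stimuli) * ncol(pairs))
  k <- 0L
  for (stim in stimuli) {
    sub <- select_stimulus(rt, stim)
    sub <- sub[seq_len(n_use), , drop = FALSE]
    for (pp in seq_len(ncol(pairs))) {
      i <- pairs[1L, pp]; j <- pairs[2L, pp]
      res <- short_term_test(sub[, i], sub[, j], null, alpha = level)
      cls <- if (is.na(stationary[i]) || is.na(stationary[j])) {
        NA_character_
      } else if (stationary[i] && stationary[j]) {
        "s-s"
      } else if (!stationary[i] && !stationary[j]) {
        "n-n"
      } else "s-n"
      k <- k + 1L
      rows[[k]] <- data.frame(stimulus = stim, neuron_i = i, neuron_j = j,
                              rho = res$statistic, p_value = res$p_value,
                              significant = res$significant,
                              pair_class = cls,
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "stationary") <- stationary
  attr(out, "bonferroni_level") <- level
  out
}
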