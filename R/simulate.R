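# Generators for the benchmark and session simulations: baseline trend
# families, correlated Gaussian noise, multi-neuron populations, the
# drift-bias scenario, and full stimulus-structured sessions.

#' Baseline trend specification
#'
#' Describes one of the slow baseline-drift families used in the
#' benchmarks:
#' * `constant` — flat at `level`.
#' * `linear` — `intercept + slope * (t - 1)`.
#' * `stepwise` — piecewise-constant `levels` changing at `change_points`
#'   (trial indices at which the next level starts).
#' * `sinusoid` — `amplitude * sin(2 * pi * n_cycles * (t - 1) / n +
#'   phase)`, exactly `n_cycles` full periods over the series (default 7
#'   cycles, amplitude 0.5). The default amplitude keeps the within-pair
#'   signal change small enough that the estimator's second-order drift
#'   bias stays below 0.01 at 7 cycles per 100 trials — the regime in
#'   which the local-detrending model's locally-constant-signal
#'   assumption holds.
#' * `arima021` — a twice-integrated MA(1) process: innovations of SD
#'   `innovation_sd` are passed through an MA(1) filter with coefficient
#'   `theta` (default 0.6) and cumulatively summed twice, giving the
#'   smooth, unreproducible wandering baselines of the correlogram
#'   benchmark.
#'
#' @param family one of `"constant"`, `"linear"`, `"stepwise"`,
#'   `"sinusoid"`, `"arima021"`.
#' @param n series length (>= 2).
#' @param level,intercept,slope,change_points,levels,amplitude,n_cycles,phase,theta,innovation_sd
#'   family-specific parameters; see above.
#' @return a `trend_spec` list.
#' @export
trend_spec <- function(family = c("constant", "linear", "stepwise",
                                  "sinusoid", "arima021"),
                       n,
                       level = 0, intercept = 0, slope = 0,
                       change_points = integer(), levels = 0,
                       amplitude = 0.5, n_cycles = 7, phase = 0,
                       theta = 0.6, innovation_sd = 0.02) {
  family <- match.arg(family)
  n <- as.integer(n)
  if (n < 2L) stop("n must be >= 2", call. = FALSE)
  if (family == "sinusoid" && n_cycles <= 0) {
    stop("n_cycles must be positive", call. = FALSE)
  }
  structure(list(family = family, n = n, level = level,
                 intercept = intercept, slope = slope,
                 change_points = as.integer(change_points),
                 levels = levels, amplitude = amplitude,
                 n_cycles = n_cycles, phase = phase, theta = theta,
                 innovation_sd = innovation_sd),
            class = "trend_spec")
}

#' Simulate a baseline trend
#'
#' Realizes a [trend_spec()]. Only the `arima021` family is stochastic;
#' all realizations are deterministic given `seed`.
#'
#' @param spec a `trend_spec`.
#' @param seed integer seed (used by the `arima021` family).
#' @return numeric vector of length `spec$n`.
#' @export
simulate_trend <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "trend_spec"))
  n <- spec$n
  switch(spec$family,
    constant = rep(spec$level, n),
    linear = spec$intercept + spec$slope * (seq_len(n) - 1),
    stepwise = {
      lev <- rep(spec$levels, length.out = length(spec$change_points) + 1L)
      idx <- findInterval(seq_len(n), c(1L, spec$change_points))
      lev[idx]
    },
    sinusoid = spec$amplitude *
      sin(2 * pi * spec$n_cycles * (seq_len(n) - 1) / n + spec$phase),
    arima021 = with_seed_(seed, {
      e <- stats::rnorm(n + 1L, sd = spec$innovation_sd)
      w <- e[-1L] + spec$theta * e[-(n + 1L)]
      cumsum(cumsum(w))
    })
  )
}

#' Bivariate noise specification
#'
#' Noise variances of the two neurons and their correlation; the implied
#' covariance matrix `[[s11, s12], [s12, s22]]` with
#' `s12 = rho * sqrt(s11 * s22)` must be positive definite.
#'
#' @param s11,s22 noise variances (> 0); default 1.
#' @param rho noise correlation in (-1, 1); default 0.3.
#' @return a `noise_spec` list with the covariance matrix in `$sigma`.
#' @export
noise_spec <- function(s11 = 1, s22 = 1, rho = 0.3) {
  if (s11 <= 0 || s22 <= 0) stop("variances must be positive", call. = FALSE)
  if (abs(rho) >= 1) stop("rho must be in (-1, 1)", call. = FALSE)
  s12 <- rho * sqrt(s11 * s22)
  structure(list(s11 = s11, s22 = s22, rho = rho,
                 sigma = matrix(c(s11, s12, s12, s22), 2L)),
            class = "noise_spec")
}

#' Simulate a drifting pair of neurons
#'
#' Adds per-trial bivariate Gaussian noise to the two baseline trends:
#' `x[t] = trend_x[t] + e_x[t]`, `y[t] = trend_y[t] + e_y[t]` with
#' `(e_x, e_y)` iid across trials (intertrial intervals are assumed long
#' enough to wash out temporal noise correlations) and covariance from
#' the [noise_spec()].
#'
#' @param trend_x,trend_y numeric baseline trends of equal length.
#' @param noise a `noise_spec`.
#' @param seed integer seed.
#' @return list with numeric vectors `x` and `y`.
#' @export
simulate_pair <- function(trend_x, trend_y, noise = noise_spec(),
                          seed = NULL) {
  if (length(trend_x) != length(trend_y)) {
    stop("trends must have equal length", call. = FALSE)
  }
  n <- length(trend_x)
  e <- with_seed_(seed, MASS::mvrnorm(n, c(0, 0), noise$sigma))
  list(x = trend_x + e[, 1L], y = trend_y + e[, 2L])
}

#' Simulate a trend-sharing population
#'
#' All `n_neurons` neurons share the same baseline trend; neurons 1 and 2
#' receive bivariate noise from `pair_noise` (the only correlated pair),
#' the remaining neurons independent unit-variance Gaussian noise — the
#' configuration of the Kalman-comparator benchmark.
#'
#' @param n_neurons number of neurons (>= 2).
#' @param trend shared baseline trend vector.
#' @param pair_noise a `noise_spec` for neurons 1-2.
#' @param seed integer seed.
#' @return numeric matrix, trials x neurons.
#' @export
simulate_population <- function(n_neurons, trend,
                                pair_noise = noise_spec(), seed = NULL) {
  n_neurons <- as.integer(n_neurons)
  if (n_neurons < 2L) stop("need at least 2 neurons", call. = FALSE)
  n <- length(trend)
  with_seed_(seed, {
    X <- matrix(0, n, n_neurons)
    e <- MASS::mvrnorm(n, c(0, 0), pair_noise$sigma)
    X[, 1L] <- trend + e[, 1L]
    X[, 2L] <- trend + e[, 2L]
    if (n_neurons > 2L) {
      X[, -(1:2)] <- trend +
        matrix(stats::rnorm(n * (n_neurons - 2L)), n)
    }
    X
  })
}

#' Simulate the alternating-mean drift-bias scenario
#'
#' Each consecutive trial pair has means `(mu - eps, mu + eps)` with
#' independent `N(0, sigma^2)` noise in both series: the configuration in
#' which the within-pair mean difference `2 * eps` leaks into the local
#' variance estimate as a second-order bias,
#' `E[s11] = sigma^2 + 2 * eps^2`.
#'
#' @param mu common mean level.
#' @param eps half the within-pair mean difference.
#' @param sigma noise SD (> 0).
#' @param n_pairs number of consecutive-trial pairs.
#' @param seed integer seed.
#' @return list with vectors `x` and `y` of length `2 * n_pairs`.
#' @export
simulate_drift_bias_pair <- function(mu, eps, sigma, n_pairs,
                                     seed = NULL) {
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  n <- 2L * as.integer(n_pairs)
  means <- rep(c(mu - eps, mu + eps), n_pairs)
  with_seed_(seed, list(x = means + stats::rnorm(n, sd = sigma),
                        y = means + stats::rnorm(n, sd = sigma)))
}

# Default circular-Gaussian tuning curves: n_neurons x n_stimuli mean
# firing rates (spikes/s), preferred stimuli equally spaced.
default_tuning <- function(n_neurons, n_stimuli = 16L,
                           baseline = 5, gain = 15, width = 0.4) {
  pref <- seq(0, n_stimuli - 1L, length.out = n_neurons + 1L)[seq_len(n_neurons)]
  t(vapply(pref, function(p) {
    ang <- 2 * pi * (seq_len(n_stimuli) - 1L - p) / n_stimuli
    baseline + gain * exp((cos(ang) - 1) / width)
  }, numeric(n_stimuli)))
}

#' Session simulation specification
#'
#' Describes a full stimulus-structured session: `n_blocks` blocks in
#' which each of `n_stimuli` stimuli appears once in pseudo-random order
#' (the reference design is 40 blocks of 16 stimuli = 640 trials), trial
#' durations uniform on `duration_range` seconds, per-neuron tuning
#' curves, an optional additive baseline drift shared across stimuli, and
#' Gaussian rate noise with covariance `noise_cov` (optionally a
#' correlated pair via `pair_rho` between neurons 1 and 2).
#'
#' @param n_neurons number of neurons.
#' @param n_stimuli stimuli per block, default 16.
#' @param n_blocks blocks per session, default 40.
#' @param tuning `n_neurons x n_stimuli` matrix of mean rates (spikes/s);
#'   default circular-Gaussian tuning curves.
#' @param drift a [trend_spec()] with `n = n_blocks * n_stimuli` applied
#'   additively to all neurons' rates, a list of one spec per neuron, or
#'   `NULL` for no drift.
#' @param noise_sd common rate-noise SD (spikes/s), default 2.
#' @param pair_rho noise correlation planted between neurons 1 and 2,
#'   default 0.
#' @param noise_cov optional full `n_neurons x n_neurons` noise
#'   covariance overriding `noise_sd`/`pair_rho`.
#' @param duration_range trial-duration range in seconds, default
#'   `c(1.0, 1.7)`.
#' @return a `session_spec` list.
#' @export
session_spec <- function(n_neurons, n_stimuli = 16L, n_blocks = 40L,
                         tuning = NULL, drift = NULL,
                         noise_sd = 2, pair_rho = 0, noise_cov = NULL,
                         duration_range = c(1.0, 1.7)) {
  n_neurons <- as.integer(n_neurons)
  if (is.null(tuning)) tuning <- default_tuning(n_neurons, n_stimuli)
  stopifnot(nrow(tuning) == n_neurons, ncol(tuning) == n_stimuli)
  if (is.null(noise_cov)) {
    noise_cov <- diag(noise_sd^2, n_neurons)
    noise_cov[1L, 2L] <- noise_cov[2L, 1L] <- pair_rho * noise_sd^2
  }
  structure(list(n_neurons = n_neurons, n_stimuli = as.integer(n_stimuli),
                 n_blocks = as.integer(n_blocks), tuning = tuning,
                 drift = drift, noise_cov = noise_cov,
                 duration_range = duration_range),
            class = "session_spec")
}

#' Simulate a full stimulus-structured session
#'
#' Draws a pseudo-random stimulus order (each block a fresh permutation of
#' all stimuli), trial durations uniform on the spec's range, per-trial
#' mean rates `tuning[neuron, stimulus] + drift[neuron, trial]`, adds
#' multivariate Gaussian rate noise with the spec's covariance, multiplies
#' by the duration, floors at 0 and rounds to integer spike counts.
#'
#' @param spec a [session_spec()].
#' @param seed integer seed; identical spec + seed give identical
#'   sessions.
#' @return a validated `session_data`.
#' @export
simulate_session <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "session_spec"))
  n_trials <- spec$n_blocks * spec$n_stimuli
  drift <- spec$drift
  with_seed_(seed, {
    stimulus <- as.vector(vapply(seq_len(spec$n_blocks),
                                 function(b) sample.int(spec$n_stimuli),
                                 integer(spec$n_stimuli)))
    duration <- stats::runif(n_trials, spec$duration_range[1L],
                             spec$duration_range[2L])
    mean_rate <- t(spec$tuning[, stimulus, drop = FALSE])
    if (!is.null(drift)) {
      dmat <- if (inherits(drift, "trend_spec")) {
        matrix(simulate_trend(drift), n_trials, spec$n_neurons)
      } else {
        vapply(drift, simulate_trend, numeric(n_trials))
      }
      mean_rate <- mean_rate + dmat
    }
    noise <- MASS::mvrnorm(n_trials, rep(0, spec$n_neurons),
                           spec$noise_cov)
    rates <- pmax(mean_rate + noise, 0)
    counts <- round(rates * duration)
    session_data(counts = counts,
                 stimulus = sprintf("s%02d", stimulus - 1L),
                 duration = duration)
  })
}
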