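# Conventional detrending baselines the short-term estimator is compared
# against: moving-average residuals and a scalar-latent Kalman state space.

#' Moving-average detrending of a trial series
#'
#' For odd windows `w = 2k+1`, the residual at each interior trial is the
#' activity minus the centred window mean; the `k` trials at each edge are
#' truncated (no partial windows). For `window = 2`, the pairing-based
#' variant: within each consecutive pair \{2t-1, 2t\} the residual is the
#' deviation from the pair mean, i.e. \eqn{\pm\Delta x_t/2} — the same
#' local detrending the short-term estimator uses.
#'
#' @param series numeric per-trial series.
#' @param window 2 or an odd integer >= 3, at most `length(series)`.
#' @return numeric residual vector (shortened by `window - 1` for odd
#'   windows; an odd final trial is dropped for `window = 2`).
#' @export
#' @examples
#' moving_average_detrend(c(1, 3, 10, 14), 2)  # -1  1 -2  2
moving_average_detrend <- function(series, window) {
  series <- as.numeric(series)
  window <- as.integer(window)
  n <- length(series)
  if (window < 2L) stop("window must be >= 2", call. = FALSE)
  if (window > n) stop("window larger than series length", call. = FALSE)
  if (window == 2L) {
    n_use <- n - n %% 2L
    if (n_use < n) warning("odd number of trials; dropping the final trial")
    x <- series[seq_len(n_use)]
    odd <- seq(1L, n_use, by = 2L)
    pm <- (x[odd] + x[odd + 1L]) / 2
    res <- x
    res[odd] <- x[odd] - pm
    res[odd + 1L] <- x[odd + 1L] - pm
    return(res)
  }
  if (window %% 2L == 0L) {
    stop("window must be 2 or an odd integer", call. = FALSE)
  }
  k <- (window - 1L) %/% 2L
  sm <- stats::filter(series, rep(1 / window, window), sides = 2)
  idx <- seq(k + 1L, n - k)
  series[idx] - as.numeric(sm)[idx]
}

#' Moving-average residual moments and correlation for a pair
#'
#' Applies [moving_average_detrend()] to both series and summarises the
#' residuals. For `window = 2` the variance/covariance estimates are the
#' uncentred residual mean squares and cross-products (the pair means are
#' already removed), which equal exactly half the local pairwise
#' covariance estimates — so the residual variances and covariance are
#' biased downward by a factor 2 (true (1, 1, 0.2) is estimated around
#' (0.5, 0.5, 0.1) on average) while their correlation ratio coincides
#' with [short_term_correlation()] to machine precision. For odd windows
#' the centred sample moments of the common residual range are used; the
#' downward bias grows with window size on rapidly changing trends.
#'
#' @inheritParams local_pair_covariances
#' @param window as in [moving_average_detrend()].
#' @return list with `var1`, `var2`, `cov`, `cor` (`NA` when degenerate)
#'   and `window`.
#' @export
ma_residual_moments <- function(x, y, window) {
  if (window == 2L) {
    # residuals are +/- Delta/2, so the uncentred residual moments are
    # exactly half the local pairwise covariance estimates and the
    # correlation ratio is identical to the short-term estimator
    e <- suppressWarnings(local_pair_covariances(x, y))
    return(list(var1 = e$s11 / 2, var2 = e$s22 / 2, cov = e$s12 / 2,
                cor = e$rho, window = 2L))
  }
  rx <- moving_average_detrend(x, window)
  ry <- moving_average_detrend(y, window)
  {
    v1 <- stats::var(rx)
    v2 <- stats::var(ry)
    cv <- stats::cov(rx, ry)
    rr <- if (v1 * v2 > 0) cv / sqrt(v1 * v2) else NA_real_
  }
  list(var1 = v1, var2 = v2, cov = cv, cor = rr, window = window)
}

#' Moving-average residual correlation
#'
#' Convenience wrapper returning only the residual correlation from
#' [ma_residual_moments()].
#'
#' @inheritParams ma_residual_moments
#' @return numeric scalar or `NA`.
#' @export
ma_residual_correlation <- function(x, y, window) {
  ma_residual_moments(x, y, window)$cor
}

# One pass of the scalar-state Kalman filter.
# model: list(F, G (p-vector), q, r (p-vector), mu0, P0).
# Returns loglik, filtered means m, posterior variances Ppost, priors a, P.
kalman_filter_ <- function(data, model) {
  data <- as.matrix(data)
  Tn <- nrow(data); p <- ncol(data)
  Fc <- model$F; G <- model$G; q <- model$q; r <- model$r
  rinv <- 1 / r
  c_gg <- sum(G^2 * rinv)
  a <- numeric(Tn); P <- numeric(Tn)
  m <- numeric(Tn); Pp <- numeric(Tn)
  a[1L] <- model$mu0; P[1L] <- model$P0
  ll <- 0
  for (t in seq_len(Tn)) {
    v <- data[t, ] - G * a[t]
    denom <- 1 + P[t] * c_gg
    gv <- sum(G * rinv * v)
    quad <- sum(v^2 * rinv) - P[t] * gv^2 / denom
    ll <- ll - 0.5 * (p * log(2 * pi) + sum(log(r)) + log(denom) + quad)
    m[t] <- a[t] + P[t] * gv / denom
    Pp[t] <- P[t] / denom
    if (t < Tn) {
      a[t + 1L] <- Fc * m[t]
      P[t + 1L] <- Fc^2 * Pp[t] + q
    }
  }
  list(loglik = ll, m = m, Ppost = Pp, a = a, P = P)
}

#' Fit the scalar-latent state-space trend model by maximum likelihood
#'
#' Fits the linear-Gaussian model
#' \deqn{\mu_{t+1} = F \mu_t + \eta, \qquad X_t^{(i)} = G^{(i)} \mu_t +
#'   \xi_i,} with a single latent trend \eqn{\mu_t} shared by all neurons,
#' per-neuron loadings \eqn{G}, trend innovation variance \eqn{q =
#' Var(\eta)} and observation noise variances \eqn{r_i = Var(\xi_i)}, by
#' numerical optimization (BFGS) of the Kalman-filter prediction-error
#' log likelihood. Variances are optimized on the log scale with a floor
#' of 1e-8. Initialization: `F = 1` (random-walk prior), `G` at the
#' per-neuron SD scale, `q` and `r` from an even variance split of the
#' first differences. Deterministic given the data.
#'
#' @param data numeric matrix, trials x neurons (>= 2 neurons, >= 10
#'   trials).
#' @param maxit BFGS iteration cap, default 200.
#' @return object of class `state_space_model`: list with `F`, `G`, `q`,
#'   `r`, `mu0`, `P0`, `loglik`, `converged`.
#' @export
fit_state_space <- function(data, maxit = 200L) {
  data <- as.matrix(data)
  Tn <- nrow(data); p <- ncol(data)
  if (p < 2L) stop("need at least 2 neurons", call. = FALSE)
  if (Tn < 10L) stop("need at least 10 trials", call. = FALSE)
  floor_v <- 1e-8
  sds <- apply(data, 2, stats::sd)
  sds[sds == 0] <- 1
  vd <- apply(diff(data), 2, stats::var)
  vd[vd == 0] <- 1e-4
  G0 <- sds
  q0 <- max(mean(vd) / (4 * mean(G0^2)), 1e-4)
  r0 <- pmax(vd / 4, 1e-4)
  mu0 <- mean(data[1L, ] / G0)
  P0 <- 100 * max(sds)^2
  theta0 <- c(1, G0, log(q0), log(r0))
  negll <- function(theta) {
    model <- list(F = theta[1L],
                  G = theta[1L + seq_len(p)],
                  q = exp(theta[p + 2L]) + floor_v,
                  r = exp(theta[p + 2L + seq_len(p)]) + floor_v,
                  mu0 = mu0, P0 = P0)
    if (abs(model$F) > 1.5) return(1e10)
    ll <- kalman_filter_(data, model)$loglik
    if (!is.finite(ll)) 1e10 else -ll
  }
  fit <- stats::optim(theta0, negll, method = "BFGS",
                      control = list(maxit = maxit))
  theta <- fit$par
  structure(list(F = theta[1L],
                 G = theta[1L + seq_len(p)],
                 q = exp(theta[p + 2L]) + floor_v,
                 r = exp(theta[p + 2L + seq_len(p)]) + floor_v,
                 mu0 = mu0, P0 = P0,
                 loglik = -fit$value,
                 converged = fit$convergence == 0L),
            class = "state_space_model")
}

#' @export
print.state_space_model <- function(x, ...) {
  cat(sprintf("<state_space_model> F=%.3f q=%.4g loglik=%.2f converged=%s\n",
              x$F, x$q, x$loglik, x$converged))
  invisible(x)
}

#' Residual correlation after Kalman trend removal
#'
#' Removes the estimated latent trend from each neuron (loading times the
#' filtered — one-sided — state estimate by default, the smoothed
#' estimate optionally) and returns the Pearson correlation of the target
#' pair's residuals. With few neurons the filtered trend absorbs part of
#' the shared noise, attenuating the residual correlation; the bias
#' shrinks as more trend-sharing neurons are added.
#'
#' @param data numeric matrix, trials x neurons.
#' @param model a fitted [fit_state_space()] model, or `NULL` to fit one.
#' @param pair length-2 integer vector of target neuron columns.
#' @param smoothed use the fixed-interval smoother instead of the filter.
#' @return numeric residual correlation (or `NA` if degenerate).
#' @export
kalman_residual_correlation <- function(data, model = NULL,
                                        pair = c(1L, 2L),
                                        smoothed = FALSE) {
  data <- as.matrix(data)
  if (is.null(model)) model <- fit_state_space(data)
  kf <- kalman_filter_(data, model)
  state <- kf$m
  if (smoothed) {
    Tn <- length(kf$m)
    s <- kf$m; Ps <- kf$Ppost
    for (t in seq(Tn - 1L, 1L)) {
      J <- kf$Ppost[t] * model$F / kf$P[t + 1L]
      s[t] <- kf$m[t] + J * (s[t + 1L] - kf$a[t + 1L])
      Ps[t] <- kf$Ppost[t] + J^2 * (Ps[t + 1L] - kf$P[t + 1L])
    }
    state <- s
  }
  res <- data - outer(state, model$G)
  rx <- res[, pair[1L]]; ry <- res[, pair[2L]]
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(NA_real_)
  stats::cor(rx, ry)
}
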