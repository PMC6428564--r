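# Linear-discriminant decoding of stimulus identity from per-trial
# population rates, with train/test schemes that dissociate the impacts
# of short-term and long-term correlated variability.

# Within-stimulus occurrence indices: list per stimulus of the row
# indices of its trials in temporal order.
stim_occurrences <- function(rt) {
  stimuli <- sort(unique(rt$stimulus))
  lapply(stats::setNames(stimuli, stimuli), function(s) {
    idx <- which(rt$stimulus == s)
    idx[order(rt$trial_index[idx])]
  })
}

#' Train/test split for one decoding scheme
#'
#' The four learning schemes, defined by within-stimulus occurrence order
#' (with 40 trials per stimulus, "former" = occurrences 1-20 and
#' "latter" = 21-40):
#' * `former_former` — train and test on the former half,
#'   cross-validated leave-one-out (the split returns the former indices
#'   with `loo = TRUE`).
#' * `former_latter` — train on former, test on latter.
#' * `former_latter_detrended` — as `former_latter`, but each period's
#'   per-neuron global mean is removed first (see
#'   [detrend_by_period_mean()]).
#' * `even_odd` — train on even-numbered occurrences, test on
#'   odd-numbered ones (which interleaves former and latter trials and is
#'   therefore homogeneous under drift).
#'
#' @param rt a `rate_table`.
#' @param scheme scheme name, see above.
#' @return list with integer vectors `train` and `test` (trial row
#'   indices), and flags `loo` and `detrend`.
#' @export
split_by_scheme <- function(rt, scheme = c("former_former",
                                           "former_latter",
                                           "former_latter_detrended",
                                           "even_odd")) {
  scheme <- match.arg(scheme)
  occ <- stim_occurrences(rt)
  counts <- lengths(occ)
  if (any(counts < 4L) || any(counts %% 2L != 0L)) {
    stop("each stimulus needs an even number (>= 4) of trials",
         call. = FALSE)
  }
  halves <- lapply(occ, function(idx) {
    h <- length(idx) %/% 2L
    list(former = idx[seq_len(h)], latter = idx[h + seq_len(h)],
         even = idx[seq_along(idx) %% 2L == 0L],
         odd = idx[seq_along(idx) %% 2L == 1L])
  })
  pick <- function(which) unlist(lapply(halves, `[[`, which), use.names = FALSE)
  switch(scheme,
    former_former = list(train = pick("former"), test = pick("former"),
                         loo = TRUE, detrend = FALSE),
    former_latter = list(train = pick("former"), test = pick("latter"),
                         loo = FALSE, detrend = FALSE),
    former_latter_detrended = list(train = pick("former"),
                                   test = pick("latter"),
                                   loo = FALSE, detrend = TRUE),
    even_odd = list(train = pick("even"), test = pick("odd"),
                    loo = FALSE, detrend = FALSE))
}

#' Remove each period's per-neuron global mean
#'
#' For the detrended former/latter scheme: from every trial of the
#' training (former) period, subtract that period's per-neuron mean
#' across all stimuli; likewise for the test (latter) period with its own
#' mean. This centres both periods (idempotently), cancelling an additive
#' between-period baseline shift while leaving tuning differences intact.
#'
#' @param train_x,test_x numeric matrices, trials x neurons.
#' @return list with centred `train` and `test` matrices.
#' @export
detrend_by_period_mean <- function(train_x, test_x) {
  list(train = sweep(train_x, 2L, colMeans(train_x)),
       test = sweep(test_x, 2L, colMeans(test_x)))
}

#' Multi-class linear discriminant classification
#'
#' Standard linear discriminant analysis with pooled within-class
#' covariance and equal class priors (the design is balanced): a test
#' trial is assigned to the class maximizing
#' `x' W^-1 mu_c - mu_c' W^-1 mu_c / 2`. The pooled covariance is
#' regularized as `W + ridge * (tr(W)/p) * I`; with 16 classes and few
#' training trials per class `W` is often near-singular, and
#' `ridge = 0` on a singular `W` raises an error instructing ridge use.
#'
#' @param train_x,test_x numeric matrices, trials x neurons.
#' @param train_y,test_y class labels.
#' @param ridge relative ridge coefficient, default 1e-6.
#' @return object of class `classification_result`: list with
#'   `success_rate`, `n_test`, `predicted`, `scheme` (filled by
#'   [decode_session()]).
#' @export
lda_decode <- function(train_x, train_y, test_x, test_y, ridge = 1e-6) {
  train_x <- as.matrix(train_x); test_x <- as.matrix(test_x)
  train_y <- as.character(train_y); test_y <- as.character(test_y)
  classes <- sort(unique(train_y))
  if (length(classes) < 2L) stop("need at least 2 classes", call. = FALSE)
  p <- ncol(train_x)
  mu <- t(vapply(classes, function(cl) {
    colMeans(train_x[train_y == cl, , drop = FALSE])
  }, numeric(p)))
  centered <- train_x - mu[match(train_y, classes), , drop = FALSE]
  W <- crossprod(centered) / (nrow(train_x) - length(classes))
  if (ridge > 0) {
    W <- W + diag(ridge * sum(diag(W)) / p, p)
  }
  Winv <- tryCatch(solve(W), error = function(e) {
    stop("pooled covariance is singular; use a positive `ridge`",
         call. = FALSE)
  })
  disc <- test_x %*% Winv %*% t(mu) -
    matrix(0.5 * rowSums((mu %*% Winv) * mu),
           nrow(test_x), length(classes), byrow = TRUE)
  predicted <- classes[max.col(disc, ties.method = "first")]
  structure(list(success_rate = mean(predicted == test_y),
                 n_test = length(test_y),
                 predicted = predicted, scheme = NA_character_),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification_result> scheme=%s success=%.3f (n=%d)\n",
              x$scheme, x$success_rate, x$n_test))
  invisible(x)
}

#' Decode stimulus identity from one session
#'
#' Runs the full pipeline for one scheme: converts the session to rates
#' (if needed), splits train/test by [split_by_scheme()], applies the
#' period-mean detrending for the detrended scheme, and classifies with
#' [lda_decode()]. `former_former` is evaluated by leave-one-out within
#' the former half. Chance level is `1/n_stimuli` (6.25% with 16
#' stimuli).
#'
#' @param x a `session_data` or `rate_table`.
#' @param scheme as in [split_by_scheme()].
#' @param ridge as in [lda_decode()].
#' @return a `classification_result` with `scheme` filled in.
#' @export
decode_session <- function(x, scheme = "former_former", ridge = 1e-6) {
  rt <- if (inherits(x, "session_data")) to_rates(x) else x
  sp <- split_by_scheme(rt, scheme)
  X <- rt$rates
  y <- rt$stimulus
  if (sp$loo) {
    idx <- sp$train
    preds <- vapply(seq_along(idx), function(k) {
      tr <- idx[-k]
      lda_decode(X[tr, , drop = FALSE], y[tr],
                 X[idx[k], , drop = FALSE], y[idx[k]],
                 ridge = ridge)$predicted
    }, character(1))
    out <- structure(list(success_rate = mean(preds == y[idx]),
                          n_test = length(idx),
                          predicted = preds, scheme = scheme),
                     class = "classification_result")
    return(out)
  }
  train_x <- X[sp$train, , drop = FALSE]
  test_x <- X[sp$test, , drop = FALSE]
  if (sp$detrend) {
    d <- detrend_by_period_mean(train_x, test_x)
    train_x <- d$train; test_x <- d$test
  }
  out <- lda_decode(train_x, y[sp$train], test_x, y[sp$test],
                    ridge = ridge)
  out$scheme <- scheme
  out
}

#' Within-stimulus trial shuffling
#'
#' Independently permutes, for each neuron, the order of that neuron's
#' trials within each stimulus. Per-neuron per-stimulus marginals are
#' exactly preserved (tuning is untouched) while across-neuron
#' simultaneity — and with it any short-term noise correlation — is
#' destroyed.
#'
#' @param rt a `rate_table`.
#' @param seed integer seed.
#' @return a shuffled `rate_table`.
#' @export
trial_shuffle <- function(rt, seed = NULL) {
  stopifnot(inherits(rt, "rate_table"))
  occ <- stim_occurrences(rt)
  rates <- rt$rates
  with_seed_(seed, {
    for (idx in occ) {
      for (j in seq_len(ncol(rates))) {
        rates[idx, j] <- rates[idx[sample.int(length(idx))], j]
      }
    }
  })
  out <- rt
  out$rates <- rates
  out
}

#' Select neurons by stationarity or absence of short-term correlations
#'
#' * `criterion = "stationary"`: keep neurons whose block-averaged
#'   session-long rate series shows no significant lag-1 serial
#'   correlation at `config$alpha_nonstationarity` — neurons without
#'   long-term correlations.
#' * `criterion = "no_short_term_pair"`: keep neurons that participate in
#'   no pair whose short-term correlation is significant at the session's
#'   Bonferroni level for any stimulus.
#'
#' Downstream decoding analyses keep only sessions with more than five
#' surviving neurons.
#'
#' @param session a `session_data`.
#' @param criterion `"stationary"` or `"no_short_term_pair"`.
#' @param config a [run_config()].
#' @param null optional pre-built null distribution (see
#'   [classify_pairs()]).
#' @return integer vector of retained neuron columns (possibly empty).
#' @export
select_neurons <- function(session,
                           criterion = c("stationary",
                                         "no_short_term_pair"),
                           config = run_config(), null = NULL) {
  criterion <- match.arg(criterion)
  if (criterion == "stationary") {
    rt <- to_rates(session)
    keep <- vapply(seq_len(ncol(rt$rates)), function(i) {
      blocks <- block_average(rt$rates[, i], config$block_size)
      res <- serial_correlation_test(blocks, config$alpha_nonstationarity)
      isTRUE(!res$significant)
    }, logical(1))
    return(which(keep))
  }
  tab <- classify_pairs(session, config, null = null)
  bad <- unique(c(tab$neuron_i[tab$significant %in% TRUE],
                  tab$neuron_j[tab$significant %in% TRUE]))
  setdiff(seq_len(ncol(session$counts)), bad)
}

#' Tuning-curve principal components for former and latter halves
#'
#' For each neuron and each half of the session (former/latter
#' within-stimulus occurrences), computes the mean response to every
#' stimulus (the tuning curve), stacks the curves as rows (two per
#' neuron), and projects them onto the first two principal components.
#' Curves are centred but not variance-standardized, so weakly tuned
#' neurons are not inflated. A between-half baseline shift appears as a
#' systematic displacement of the latter-half points.
#'
#' @param rt a `rate_table`.
#' @return data.frame with `neuron`, `half` (`"former"`/`"latter"`),
#'   `pc1`, `pc2`; the rotation is in attribute `rotation`.
#' @export
tuning_curve_pca <- function(rt) {
  stopifnot(inherits(rt, "rate_table"))
  occ <- stim_occurrences(rt)
  n_neurons <- ncol(rt$rates)
  curves <- do.call(rbind, lapply(c("former", "latter"), function(half) {
    t(vapply(occ, function(idx) {
      h <- length(idx) %/% 2L
      use <- if (half == "former") idx[seq_len(h)] else idx[h + seq_len(h)]
      colMeans(rt$rates[use, , drop = FALSE])
    }, numeric(n_neurons)))
  }))
  # rows of `curves` are stimuli x (2 halves); transpose to neuron-half rows
  mat <- rbind(t(curves[seq_along(occ), , drop = FALSE]),
               t(curves[length(occ) + seq_along(occ), , drop = FALSE]))
  pca <- stats::prcomp(mat, center = TRUE, scale. = FALSE)
  out <- data.frame(neuron = rep(seq_len(n_neurons), 2L),
                    half = rep(c("former", "latter"), each = n_neurons),
                    pc1 = pca$x[, 1L], pc2 = pca$x[, 2L],
                    row.names = NULL)
  attr(out, "rotation") <- pca$rotation[, 1:2]
  out
}

#' Paired comparison of per-session success rates
#'
#' Paired t test on matched per-session classification success rates
#' under two conditions. Degenerate cases are handled explicitly: all
#' differences zero gives `t = 0, p = 1`; a constant non-zero difference
#' gives `t = +/-Inf, p = 0`.
#'
#' @param rates_a,rates_b numeric vectors of per-session success rates,
#'   matched by position.
#' @return list with `t`, `p_value`, `mean_diff`, `n_sessions`.
#' @export
paired_rate_comparison <- function(rates_a, rates_b) {
  if (length(rates_a) != length(rates_b)) {
    stop("session lists must be matched", call. = FALSE)
  }
  if (length(rates_a) < 2L) stop("need at least 2 sessions", call. = FALSE)
  d <- rates_a - rates_b
  if (stats::sd(d) == 0) {
    t_stat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    p <- if (mean(d) == 0) 1 else 0
  } else {
    tt <- stats::t.test(rates_a, rates_b, paired = TRUE)
    t_stat <- unname(tt$statistic)
    p <- tt$p.value
  }
  list(t = t_stat, p_value = p, mean_diff = mean(d),
       n_sessions = length(rates_a))
}
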