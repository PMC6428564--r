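#' Construct a trial-structured session
#'
#' A session holds the spike counts of simultaneously recorded neurons over
#' a sequence of trials together with the per-trial stimulus label, trial
#' duration and absolute temporal order. In the reference design a session
#' has 640 trials: 40 blocks in which each of 16 stimuli is presented once
#' in pseudo-random order, with trial durations between 1.0 and 1.7 s.
#'
#' @param counts integer matrix, trials x neurons, spike counts (>= 0).
#' @param stimulus per-trial stimulus labels (coerced to character).
#' @param duration per-trial durations in seconds (> 0).
#' @param trial_index per-trial absolute temporal order, strictly
#'   increasing; defaults to `1:nrow(counts)`.
#' @param neuron_ids stable neuron identifiers; defaults to `"n000"`,
#'   `"n001"`, ...
#' @return an object of class `session_data`.
#' @export
session_data <- function(counts, stimulus, duration,
                         trial_index = seq_len(nrow(counts)),
                         neuron_ids = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (is.null(neuron_ids)) {
    neuron_ids <- sprintf("n%03d", seq_len(ncol(counts)) - 1L)
  }
  dimnames(counts) <- list(NULL, neuron_ids)
  x <- structure(
    list(counts = counts,
         stimulus = as.character(stimulus),
         duration = as.numeric(duration),
         trial_index = as.integer(trial_index),
         neuron_ids = neuron_ids),
    class = "session_data")
  validate_session(x)
}

#' Validate a session object
#'
#' Checks the structural invariants: equal lengths of the per-trial fields,
#' nonnegative counts, strictly positive durations, and a strictly
#' increasing trial index. Returns the object invisibly-unchanged on
#' success, errors (naming the offending row) otherwise.
#'
#' @param x a `session_data` object.
#' @return `x`, invisibly validated.
#' @export
validate_session <- function(x) {
  stopifnot(inherits(x, "session_data"))
  n <- nrow(x$counts)
  if (length(x$stimulus) != n || length(x$duration) != n ||
      length(x$trial_index) != n) {
    stop("per-trial fields must all have length nrow(counts)", call. = FALSE)
  }
  bad <- which(x$counts < 0, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("negative spike count at row %d", bad[1L, 1L]), call. = FALSE)
  }
  bad <- which(!(x$duration > 0))
  if (length(bad) > 0L) {
    stop(sprintf("nonpositive duration at row %d", bad[1L]), call. = FALSE)
  }
  if (any(diff(x$trial_index) <= 0L)) {
    stop("trial_index must be strictly increasing", call. = FALSE)
  }
  x
}

#' @export
print.session_data <- function(x, ...) {
  cat(sprintf("<session_data> %d trials x %d neurons, %d stimuli\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$stimulus))))
  invisible(x)
}

#' Check the reference block design
#'
#' TRUE when every consecutive block of `n_stimuli` trials presents each
#' stimulus exactly once (the pseudo-random block design: 40 blocks of 16
#' stimuli in the reference sessions).
#'
#' @param session a `session_data` object.
#' @param n_stimuli block length; default 16.
#' @return logical scalar.
#' @export
check_block_design <- function(session, n_stimuli = 16L) {
  n <- length(session$stimulus)
  if (n %% n_stimuli != 0L) return(FALSE)
  labs <- sort(unique(session$stimulus))
  if (length(labs) != n_stimuli) return(FALSE)
  blocks <- split(session$stimulus, rep(seq_len(n %/% n_stimuli),
                                        each = n_stimuli))
  all(vapply(blocks, function(b) identical(sort(b), labs), logical(1)))
}

#' Read a session from a tab-separated file
#'
#' The file format is one header line and one row per trial, with columns
#' `trial_index`, `stimulus`, `duration` and one column per neuron (any
#' further columns are taken as neurons; the writer names them `n000`,
#' `n001`, ...). Rows are sorted by `trial_index` on read and all session
#' invariants are checked.
#'
#' @param path file path.
#' @param sep field delimiter, default tab.
#' @return a validated `session_data`.
#' @export
read_session <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = NA, check.names = FALSE,
                          stringsAsFactors = FALSE)
  required <- c("trial_index", "stimulus", "duration")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  neuron_cols <- setdiff(names(df), required)
  if (length(neuron_cols) == 0L) stop("no neuron columns found", call. = FALSE)
  df <- df[order(df$trial_index), , drop = FALSE]
  session_data(counts = as.matrix(df[neuron_cols]),
               stimulus = df$stimulus,
               duration = df$duration,
               trial_index = df$trial_index,
               neuron_ids = neuron_cols)
}

#' Write a session to a tab-separated file
#'
#' Inverse of [read_session()]: counts are written as integers and
#' durations with 17 significant digits so that a read/write round trip
#' reproduces the session exactly.
#'
#' @param session a `session_data`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  validate_session(session)
  df <- data.frame(trial_index = session$trial_index,
                   stimulus = session$stimulus,
                   duration = sprintf("%.17g", session$duration),
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(session$counts))
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("could not write ", path, ": ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Convert spike counts to firing rates
#'
#' Divides each trial's spike count by that trial's duration, the activity
#' feature used throughout the downstream analyses.
#'
#' @param session a `session_data`.
#' @return an object of class `rate_table` with fields `rates` (trials x
#'   neurons, spikes/s) and the session's per-trial metadata.
#' @export
to_rates <- function(session) {
  validate_session(session)
  structure(
    list(rates = session$counts / session$duration,
         stimulus = session$stimulus,
         duration = session$duration,
         trial_index = session$trial_index,
         neuron_ids = session$neuron_ids),
    class = "rate_table")
}

#' @export
print.rate_table <- function(x, ...) {
  cat(sprintf("<rate_table> %d trials x %d neurons\n",
              nrow(x$rates), ncol(x$rates)))
  invisible(x)
}

#' Extract the per-neuron trial series for one stimulus
#'
#' Returns the activity of every neuron on the trials of a single stimulus,
#' in their original temporal order. Consecutive rows are consecutive
#' occurrences of that stimulus (40 in the reference design), not
#' necessarily adjacent session trials; the estimator treats them as a
#' contiguous series.
#'
#' @param x a `session_data` (counts) or `rate_table` (rates).
#' @param stimulus a stimulus label present in `x`.
#' @return numeric matrix (occurrences x neurons) with attribute
#'   `trial_index` giving the absolute trial order of each row.
#' @export
select_stimulus <- function(x, stimulus) {
  values <- if (inherits(x, "session_data")) x$counts else x$rates
  keep <- which(x$stimulus == as.character(stimulus))
  if (length(keep) == 0L) {
    stop("unknown stimulus label: ", stimulus, call. = FALSE)
  }
  keep <- keep[order(x$trial_index[keep])]
  out <- values[keep, , drop = FALSE]
  attr(out, "trial_index") <- x$trial_index[keep]
  out
}

#' Analysis run configuration
#'
#' Bundles the tunable thresholds of the inference pipeline: the
#' nonstationarity test level, the base pairwise level (Bonferroni-divided
#' downstream), the Monte-Carlo replicate count for the null distribution,
#' and the block size of the block-averaging step.
#'
#' @param seed integer master seed; all randomness in a run flows from it
#'   through named child streams.
#' @param alpha_nonstationarity level of the serial-correlation test
#'   (default 0.01, uncorrected).
#' @param alpha_pairwise_base base level for the pairwise short-term test
#'   before Bonferroni division (default 0.01).
#' @param monte_carlo_reps Monte-Carlo replicates for the null (default
#'   1e6; reduce for quick runs).
#' @param block_size trials per block for block averaging (default 16).
#' @return a `run_config` list.
#' @export
run_config <- function(seed = 1L,
                       alpha_nonstationarity = 0.01,
                       alpha_pairwise_base = 0.01,
                       monte_carlo_reps = 1e6,
                       block_size = 16L) {
  stopifnot(alpha_nonstationarity > 0, alpha_nonstationarity < 1,
            alpha_pairwise_base > 0, alpha_pairwise_base < 1,
            monte_carlo_reps >= 1, block_size >= 1)
  structure(list(seed = as.integer(seed),
                 alpha_nonstationarity = alpha_nonstationarity,
                 alpha_pairwise_base = alpha_pairwise_base,
                 monte_carlo_reps = as.integer(monte_carlo_reps),
                 block_size = as.integer(block_size)),
            class = "run_config")
}
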