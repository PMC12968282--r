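## Event extraction: from a multichannel signal to per-channel event trains
## and inter-event interval series.

#' Construct an EEG-like signal object
#'
#' Wraps a samples-by-channels table with its sampling rate. Each column is
#' one channel; rows are consecutive samples. Time is implicit: sample `i`
#' (1-based) occurs at `(i - 1) / fs` seconds. Amplitudes are assumed to be
#' in microvolt-like units; all analysis in the package is invariant to
#' positive rescaling.
#'
#' @param x A data frame or matrix of amplitudes (samples x channels), or a
#'   numeric vector for a single channel.
#' @param fs Sampling rate in Hz (> 0).
#' @param channel_labels Optional channel names; defaults to existing column
#'   names or `ch1, ch2, ...`.
#' @return A tibble of class `eeg_signal` with one column per channel and
#'   the sampling rate stored in `attr(, "fs")`.
#' @examples
#' sig <- eeg_signal(cbind(a = rnorm(100), b = rnorm(100)), fs = 250)
#' signal_fs(sig)
#' @export
eeg_signal <- function(x, fs, channel_labels = NULL) {
  if (is.numeric(x) && is.null(dim(x))) x <- matrix(x, ncol = 1)
  x <- as.data.frame(x)
  if (ncol(x) < 1L) abort("A signal needs at least one channel.")
  if (nrow(x) < 2L) abort("A signal needs at least 2 samples per channel.")
  if (!all(vapply(x, is.numeric, logical(1)))) {
    abort("All channels must be numeric.")
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    abort("`fs` must be a single positive sampling rate in Hz.")
  }
  if (!is.null(channel_labels)) {
    if (length(channel_labels) != ncol(x)) {
      abort("`channel_labels` must match the number of channels.")
    }
    names(x) <- channel_labels
  } else if (is.null(names(x)) || any(names(x) == "") ||
    all(grepl("^V[0-9]+$", names(x)))) {
    names(x) <- paste0("ch", seq_len(ncol(x)))
  }
  out <- tibble::as_tibble(x)
  attr(out, "fs") <- fs
  class(out) <- c("eeg_signal", class(out))
  out
}

#' @rdname eeg_signal
#' @param signal An `eeg_signal` object.
#' @export
signal_fs <- function(signal) {
  fs <- attr(signal, "fs")
  if (is.null(fs)) abort("`signal` carries no sampling rate; use eeg_signal().")
  fs
}

#' @export
print.eeg_signal <- function(x, ...) {
  cat(sprintf(
    "<eeg_signal> %d channels x %d samples @ %g Hz (%.3f s)\n",
    ncol(x), nrow(x), attr(x, "fs"), nrow(x) / attr(x, "fs")
  ))
  NextMethod()
}

#' Mean and SD of the negative part of a channel
#'
#' The event threshold is anchored to the statistics of the negative-going
#' half of the signal: the subset of samples strictly below zero. Returns
#' their mean and population standard deviation (divisor `n`, not `n - 1`;
#' the difference is negligible at recording lengths but is fixed for
#' exactness).
#'
#' @param x Numeric sample vector for one channel.
#' @return A one-row tibble with columns `mean_neg`, `sd_neg`, `n_neg`.
#' @examples
#' negative_part_stats(c(-1, -1, -4, 2, 3))
#' @export
negative_part_stats <- function(x) {
  if (!is.numeric(x)) abort("`x` must be numeric.")
  neg <- x[!is.na(x) & x < 0]
  if (length(neg) < 2L) {
    abort("Channel unusable: fewer than 2 strictly negative samples.")
  }
  m <- mean(neg)
  tibble::tibble(
    mean_neg = m,
    sd_neg = sqrt(mean((neg - m)^2)),
    n_neg = length(neg)
  )
}

#' Detect sub-threshold amplitude events
#'
#' For each channel, the threshold is `mean_neg - n_sd * sd_neg`, computed
#' from the negative part of that channel only (never pooled). An event is
#' each maximal contiguous run of samples strictly below the threshold; its
#' timestamp is, by default, the time of the first sample of the run (the
#' downward crossing), in milliseconds. Channels without at least two
#' negative samples, or with no sub-threshold excursion, yield zero events;
#' unusable channels are skipped with a warning and listed in
#' `attr(, "skipped")`.
#'
#' @param signal An [eeg_signal()], or a data frame / matrix accompanied by
#'   `fs`.
#' @param n_sd Number of standard deviations below the negative-part mean
#'   (default 1, the convention motivated by the divergence of Gaussian and
#'   q-Gaussian tails beyond the central limit).
#' @param fs Sampling rate in Hz; taken from the signal when omitted.
#' @param event_time `"crossing"` (first sub-threshold sample of a run,
#'   default) or `"minimum"` (time of the run's most negative sample).
#' @return A tibble of class `event_train` with columns `channel`,
#'   `event_time_ms`, `threshold`; attributes `fs`, `duration_ms`,
#'   `skipped` (character vector of unusable channels).
#' @examples
#' x <- rep(-1, 1000); x[c(101, 301, 601)] <- -10
#' detect_events(eeg_signal(x, fs = 1000))
#' @export
detect_events <- function(signal, n_sd = 1, fs = NULL,
                          event_time = c("crossing", "minimum")) {
  event_time <- match.arg(event_time)
  if (!is.numeric(n_sd) || length(n_sd) != 1L || n_sd <= 0) {
    abort("`n_sd` must be a single positive number.")
  }
  if (is.null(fs)) {
    fs <- signal_fs(signal)
  }
  if (!inherits(signal, "eeg_signal")) signal <- eeg_signal(signal, fs = fs)
  channels <- names(signal)
  skipped <- character(0)

  one_channel <- function(ch) {
    x <- signal[[ch]]
    stats <- tryCatch(negative_part_stats(x), error = function(e) NULL)
    if (is.null(stats)) {
      skipped <<- c(skipped, ch)
      warn(sprintf("Channel '%s' skipped: no usable negative part.", ch))
      return(NULL)
    }
    thr <- stats$mean_neg - n_sd * stats$sd_neg
    below <- !is.na(x) & x < thr
    if (!any(below)) {
      return(tibble::tibble(
        channel = ch, event_time_ms = numeric(0), threshold = thr
      ))
    }
    d <- diff(c(FALSE, below))
    starts <- which(d == 1L)
    if (event_time == "minimum") {
      ends <- which(diff(c(below, FALSE)) == -1L)
      idx <- purrr::map2_int(starts, ends, function(s, e) {
        s + which.min(x[s:e]) - 1L
      })
    } else {
      idx <- starts
    }
    tibble::tibble(
      channel = ch,
      event_time_ms = (idx - 1) / fs * 1000,
      threshold = thr
    )
  }

  out <- purrr::map(channels, one_channel)
  out <- dplyr::bind_rows(out[!vapply(out, is.null, logical(1))])
  if (nrow(out) == 0 && length(skipped) == length(channels)) {
    warn("No usable channels: every channel was skipped.")
    out <- tibble::tibble(
      channel = character(0), event_time_ms = numeric(0),
      threshold = numeric(0)
    )
  }
  attr(out, "fs") <- fs
  attr(out, "duration_ms") <- nrow(signal) / fs * 1000
  attr(out, "skipped") <- skipped
  class(out) <- c("event_train", class(out))
  out
}

#' Inter-event intervals from an event train
#'
#' Successive differences of event times within each channel, in
#' milliseconds. Channels with fewer than two events contribute no
#' intervals.
#'
#' @param events An `event_train` tibble from [detect_events()], or any data
#'   frame with columns `channel` and `event_time_ms`.
#' @return A tibble with columns `channel` and `interval_ms`, all values
#'   strictly positive.
#' @examples
#' ev <- tibble::tibble(channel = "a", event_time_ms = c(100, 300, 600))
#' event_intervals(ev) # 200, 300
#' @export
event_intervals <- function(events) {
  if (!all(c("channel", "event_time_ms") %in% names(events))) {
    abort("`events` needs columns `channel` and `event_time_ms`.")
  }
  out <- events |>
    dplyr::group_by(.data$channel) |>
    dplyr::arrange(.data$event_time_ms, .by_group = TRUE) |>
    dplyr::reframe(interval_ms = diff(.data$event_time_ms))
  if (any(out$interval_ms <= 0)) {
    abort("Duplicate event times produced non-positive intervals.")
  }
  out
}
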