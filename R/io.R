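## Signal IO (delimited text + EDF) and the end-to-end pipeline.

#' Read a multichannel signal
#'
#' Delimited files (CSV or TSV, by extension or sniffing) must carry a
#' header row of channel names, one column per channel; the sampling rate
#' comes from `fs` or from a JSON sidecar `<path>.json` with a field `fs`
#' (written by [write_signal()]). EDF files carry their rate in the header.
#'
#' @param path Input file.
#' @param format `"auto"` (default; by extension), `"edf"`, or
#'   `"delimited"`.
#' @param fs Sampling rate in Hz for delimited input without a sidecar.
#' @return An [eeg_signal()]; channel order as in the file.
#' @export
read_signal <- function(path, format = c("auto", "edf", "delimited"),
                        fs = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("No such file: '%s'.", path))
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "delimited"
  }
  if (format == "edf") {
    return(read_edf(path))
  }
  sidecar <- paste0(path, ".json")
  if (is.null(fs) && file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    fs <- meta$fs
  }
  if (is.null(fs)) {
    abort(sprintf(
      "Sampling rate unavailable for '%s': pass `fs` or provide '%s'.",
      path, sidecar
    ))
  }
  delim <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  d <- readr::read_delim(path, delim = delim, show_col_types = FALSE)
  if (ncol(d) == 0 || nrow(d) == 0) abort(sprintf("'%s' contains no channels.", path))
  eeg_signal(d, fs = fs)
}

#' Write a signal to delimited text or EDF
#'
#' Delimited output is full-precision CSV/TSV with a header of channel
#' names plus a JSON sidecar holding the sampling rate (and the planted
#' ground truth, when the signal carries one), making the text round trip
#' lossless.
#'
#' @param signal An [eeg_signal()].
#' @param path Output path; `.edf` selects EDF, `.tsv`/`.txt` tab
#'   delimiters, anything else CSV.
#' @return `path`, invisibly.
#' @export
write_signal <- function(signal, path) {
  if (grepl("\\.edf$", path, ignore.case = TRUE)) {
    write_edf(signal, path)
  } else {
    delim <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
    readr::write_delim(tibble::as_tibble(signal), path, delim = delim)
  }
  gt <- attr(signal, "ground_truth")
  meta <- list(fs = signal_fs(signal))
  if (!is.null(gt)) {
    meta$ground_truth <- list(
      params = as.list(tibble::as_tibble(gt$params)[1, ]),
      event_times_ms = gt$event_times_ms,
      pulse_amplitude = gt$pulse_amplitude,
      noise_sd = gt$noise_sd,
      baseline = gt$baseline,
      seed = gt$seed
    )
  }
  jsonlite::write_json(meta, paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Run the full complexity pipeline
#'
#' read (optional) -> event detection -> inter-event intervals -> empirical
#' distribution -> q-exponential vs Boltzmann-Gibbs fits. Returns a report
#' carrying the model comparison, per-channel event and interval counts,
#' discarded-interval counts, warnings, and a complete configuration echo
#' (including the seed), sufficient to reproduce the run.
#'
#' @param input An [eeg_signal()], or a file path accepted by
#'   [read_signal()].
#' @param fs Sampling rate for delimited input without a sidecar.
#' @param n_sd Event threshold depth in negative-part SDs (default 1).
#' @param n_bins,t_min,t_max Histogram geometry (defaults 500 classes over
#'   0-1000 ms).
#' @param pooling `"pooled"` (default) or `"per_channel"`. Per-channel mode
#'   fits each channel separately.
#' @param n_starts,seed,bounds,loss Fitting configuration, see
#'   [fit_qexp()].
#' @param center_offset Quantization alignment passed to the fits (see
#'   [fit_qexp()]). The default `NULL` uses `-500 / fs` ms, half the
#'   sampling period: event times live on the sampling grid, and this
#'   removes the half-sample misalignment between integer-valued intervals
#'   and bin centers. Pass 0 to disable.
#' @param output Optional path: the report is additionally written as JSON.
#' @return A `neuroq_report` list: `comparison` (pooled) or `comparisons`
#'   (per channel), `counts` (tibble of per-channel events/intervals),
#'   `n_discarded`, `skipped_channels`, `config`, `warnings`.
#' @examples
#' sig <- synthesize_signal(qexp_params(0.14, 2.24, 1.07, 1.22),
#'   n_events = 300, seed = 7
#' )
#' rep <- run_pipeline(sig, n_starts = 8)
#' glance(rep$comparison$qexp)
#' @export
run_pipeline <- function(input, fs = NULL, n_sd = 1,
                         n_bins = 500, t_min = 0, t_max = 1000,
                         pooling = c("pooled", "per_channel"),
                         n_starts = 32, seed = 1, bounds = NULL,
                         loss = c("linear", "log"), center_offset = NULL,
                         output = NULL) {
  pooling <- match.arg(pooling)
  loss <- match.arg(loss)
  warnings <- character(0)
  wh <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      warnings <<- c(warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }
  signal <- if (is.character(input)) read_signal(input, fs = fs) else input
  if (is.null(center_offset)) center_offset <- -500 / signal_fs(signal)
  events <- wh(detect_events(signal, n_sd = n_sd, fs = fs))
  intervals <- event_intervals(events)
  counts <- dplyr::left_join(
    dplyr::count(tibble::as_tibble(events), .data$channel, name = "n_events"),
    dplyr::count(intervals, .data$channel, name = "n_intervals"),
    by = "channel"
  ) |>
    dplyr::mutate(n_intervals = dplyr::coalesce(.data$n_intervals, 0L))

  dist <- bin_intervals(intervals,
    n_bins = n_bins, t_min = t_min, t_max = t_max, pooling = pooling
  )

  if (pooling == "pooled") {
    comparison <- compare_models(dist,
      n_starts = n_starts, seed = seed, bounds = bounds, loss = loss,
      center_offset = center_offset
    )
    comparisons <- NULL
  } else {
    comparison <- NULL
    comparisons <- dist |>
      dplyr::group_by(.data$channel) |>
      dplyr::group_map(function(d, key) {
        dd <- tibble::as_tibble(d)
        for (a in c(
          "bin_edges", "bin_width", "t_min", "t_max", "n_bins"
        )) {
          attr(dd, a) <- attr(dist, a)
        }
        attr(dd, "pooling") <- "pooled"
        class(dd) <- c("interval_distribution", class(dd))
        cmp <- compare_models(dd,
          n_starts = n_starts, seed = seed, bounds = bounds, loss = loss,
          center_offset = center_offset
        )
        cmp$channel <- key$channel
        cmp
      })
  }

  config <- list(
    input = if (is.character(input)) input else "<in-memory signal>",
    fs = signal_fs(signal), n_sd = n_sd,
    n_bins = n_bins, t_min = t_min, t_max = t_max, pooling = pooling,
    n_starts = n_starts, seed = seed, loss = loss,
    center_offset = center_offset,
    package_version = as.character(utils::packageVersion("neuroq"))
  )
  report <- list(
    comparison = comparison,
    comparisons = comparisons,
    counts = counts,
    n_discarded = attr(dist, "n_discarded"),
    skipped_channels = attr(events, "skipped"),
    config = config,
    warnings = warnings
  )
  class(report) <- "neuroq_report"
  if (!is.null(output)) write_report_json(report, output)
  report
}

#' @export
print.neuroq_report <- function(x, ...) {
  cat("<neuroq_report>\n")
  cat(sprintf(
    "  channels: %d used, %d skipped; intervals discarded: %s\n",
    nrow(x$counts), length(x$skipped_channels),
    paste(x$n_discarded, collapse = ", ")
  ))
  if (!is.null(x$comparison)) {
    print(x$comparison)
  } else {
    for (cmp in x$comparisons) {
      cat(sprintf(
        "  [%s] q = %.4f (preferred: %s)\n",
        cmp$channel, cmp$qexp$params$q, cmp$preferred
      ))
    }
  }
  invisible(x)
}

#' Serialize a pipeline report to JSON
#'
#' @param report A `neuroq_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  out <- list(
    comparison = if (!is.null(report$comparison)) fit_to_list(report$comparison),
    comparisons = if (!is.null(report$comparisons)) {
      purrr::map(report$comparisons, function(cmp) {
        c(list(channel = cmp$channel), fit_to_list(cmp))
      })
    },
    counts = report$counts,
    n_discarded = report$n_discarded,
    skipped_channels = report$skipped_channels,
    config = report$config,
    warnings = report$warnings
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
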