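## Empirical interval distributions: equal-width histograms of inter-event
## intervals expressed as per-bin relative frequencies.

#' Bin inter-event intervals into an empirical probability distribution
#'
#' Builds an equal-width histogram on `[t_min, t_max)` with left-closed,
#' right-open bins and converts counts to relative frequencies
#' (count / number of in-range intervals). Intervals outside the range are
#' discarded, not clipped — clipping would distort the fitted tail — and
#' counted in `attr(, "n_discarded")`. In `"pooled"` mode intervals from
#' all channels are concatenated before binning (the convention used for
#' whole-head complexity); `"per_channel"` keeps one distribution per
#' channel.
#'
#' Canonical class counts are 100, 500 and 1000 over 0–1000 ms; the fitted
#' entropic index q is inherently relative to this binning configuration,
#' so both the count and the range are explicit arguments.
#'
#' @param intervals A tibble with column `interval_ms` (and `channel` when
#'   per-channel), as from [event_intervals()], or a bare numeric vector of
#'   intervals in ms.
#' @param n_bins Number of equal-width interval classes (>= 2; default 500).
#' @param t_min,t_max Histogram range in ms (default 0 to 1000).
#' @param pooling `"pooled"` (default) or `"per_channel"`.
#' @return A tibble of class `interval_distribution` with columns
#'   `bin_center` and `probability` (plus `channel` in per-channel mode).
#'   Attributes: `bin_edges`, `bin_width`, `n_total`, `n_discarded`,
#'   `t_min`, `t_max`, `n_bins`, `pooling`.
#' @examples
#' bin_intervals(c(200, 300), n_bins = 500)
#' @export
bin_intervals <- function(intervals, n_bins = 500, t_min = 0, t_max = 1000,
                          pooling = c("pooled", "per_channel")) {
  pooling <- match.arg(pooling)
  if (is.numeric(intervals) && is.null(dim(intervals))) {
    intervals <- tibble::tibble(channel = "pooled", interval_ms = intervals)
  }
  if (!("interval_ms" %in% names(intervals))) {
    abort("`intervals` needs a column `interval_ms`.")
  }
  if (!is.numeric(n_bins) || length(n_bins) != 1L || n_bins < 2 ||
    n_bins != round(n_bins)) {
    abort("`n_bins` must be a whole number >= 2.")
  }
  if (!(t_max > t_min && t_min >= 0)) {
    abort("Need t_max > t_min >= 0.")
  }
  edges <- seq(t_min, t_max, length.out = n_bins + 1)
  width <- (t_max - t_min) / n_bins
  centers <- edges[-1] - width / 2

  hist_one <- function(x) {
    inr <- x >= t_min & x < t_max
    counts <- tabulate(
      pmin(floor((x[inr] - t_min) / width) + 1L, n_bins),
      nbins = n_bins
    )
    list(counts = counts, n_in = sum(inr), n_out = sum(!inr))
  }

  if (pooling == "pooled") {
    hh <- hist_one(intervals$interval_ms)
    if (hh$n_in == 0L) {
      abort("No intervals fall inside [t_min, t_max); nothing to bin.")
    }
    out <- tibble::tibble(
      bin_center = centers,
      probability = hh$counts / hh$n_in
    )
    n_total <- hh$n_in
    n_discarded <- hh$n_out
  } else {
    if (!("channel" %in% names(intervals))) {
      abort("Per-channel pooling needs a `channel` column.")
    }
    per <- intervals |>
      dplyr::group_by(.data$channel) |>
      dplyr::group_map(function(d, key) {
        hh <- hist_one(d$interval_ms)
        if (hh$n_in == 0L) {
          abort(sprintf(
            "Channel '%s' has no intervals inside [t_min, t_max).",
            key$channel
          ))
        }
        tibble::tibble(
          channel = key$channel,
          bin_center = centers,
          probability = hh$counts / hh$n_in,
          .n_in = hh$n_in, .n_out = hh$n_out
        )
      })
    out <- dplyr::bind_rows(per)
    n_total <- setNames(
      vapply(per, function(d) d$.n_in[1], integer(1)),
      vapply(per, function(d) d$channel[1], character(1))
    )
    n_discarded <- setNames(
      vapply(per, function(d) d$.n_out[1], integer(1)),
      names(n_total)
    )
    out$.n_in <- NULL
    out$.n_out <- NULL
  }

  attr(out, "bin_edges") <- edges
  attr(out, "bin_width") <- width
  attr(out, "n_total") <- n_total
  attr(out, "n_discarded") <- n_discarded
  attr(out, "t_min") <- t_min
  attr(out, "t_max") <- t_max
  attr(out, "n_bins") <- as.integer(n_bins)
  attr(out, "pooling") <- pooling
  class(out) <- c("interval_distribution", class(out))
  out
}

#' Noiseless model-implied interval distribution
#'
#' Evaluates a fitted-model law on a histogram grid: per-bin probability =
#' bin width x density at the bin center. Useful for round-trip fitting
#' experiments where the ground truth is the law itself rather than sampled
#' data. Note the result sums to the model's probability mass inside
#' `[t_min, t_max)` up to midpoint-rule error, not exactly to 1; it is left
#' unnormalized on purpose so that it matches the fitted model family
#' exactly.
#'
#' @param params A [qexp_params()] or [bg_params()] object.
#' @param n_bins,t_min,t_max Histogram geometry as in [bin_intervals()].
#' @return An `interval_distribution` tibble (with `n_total = NA`, as no
#'   intervals were counted).
#' @examples
#' model_distribution(qexp_params(0.14, 2.24, 1.07, 1.22))
#' @export
model_distribution <- function(params, n_bins = 500, t_min = 0, t_max = 1000) {
  edges <- seq(t_min, t_max, length.out = n_bins + 1)
  width <- (t_max - t_min) / n_bins
  centers <- edges[-1] - width / 2
  dens <- if (inherits(params, "bg_params")) {
    bg_pdf(centers, params)
  } else {
    qexp_pdf(centers, params)
  }
  out <- tibble::tibble(bin_center = centers, probability = width * dens)
  attr(out, "bin_edges") <- edges
  attr(out, "bin_width") <- width
  attr(out, "n_total") <- NA_integer_
  attr(out, "n_discarded") <- NA_integer_
  attr(out, "t_min") <- t_min
  attr(out, "t_max") <- t_max
  attr(out, "n_bins") <- as.integer(n_bins)
  attr(out, "pooling") <- "model"
  class(out) <- c("interval_distribution", class(out))
  out
}

#' Coarsen an interval distribution by an integer factor
#'
#' Merges consecutive bins `factor`-to-1, summing probabilities, weighted by
#' counts when channels differ in totals. A 1000-class histogram coarsened
#' 2:1 reproduces the 500-class histogram of the same data exactly.
#'
#' @param dist An `interval_distribution`.
#' @param factor Positive integer dividing the number of bins.
#' @return A coarser `interval_distribution`.
#' @export
coarsen_distribution <- function(dist, factor) {
  n_bins <- attr(dist, "n_bins")
  if (factor < 1 || n_bins %% factor != 0) {
    abort("`factor` must divide the number of bins.")
  }
  if (attr(dist, "pooling") == "per_channel") {
    abort("Coarsen per-channel distributions one channel at a time.")
  }
  grp <- rep(seq_len(n_bins / factor), each = factor)
  edges <- attr(dist, "bin_edges")[seq(1, n_bins + 1, by = factor)]
  width <- attr(dist, "bin_width") * factor
  out <- tibble::tibble(
    bin_center = edges[-1] - width / 2,
    probability = as.numeric(tapply(dist$probability, grp, sum))
  )
  for (a in c("n_total", "n_discarded", "t_min", "t_max", "pooling")) {
    attr(out, a) <- attr(dist, a)
  }
  attr(out, "bin_edges") <- edges
  attr(out, "bin_width") <- width
  attr(out, "n_bins") <- as.integer(n_bins / factor)
  class(out) <- c("interval_distribution", class(out))
  out
}

#' Write / read an interval distribution as delimited text
#'
#' Two columns, `bin_center` and `probability`, with the histogram geometry
#' in a JSON sidecar (`<path>.json`) so that a round trip is lossless.
#'
#' @param dist An `interval_distribution`.
#' @param path Output file (CSV).
#' @return `path`, invisibly (writer); an `interval_distribution` (reader).
#' @export
write_distribution <- function(dist, path) {
  readr::write_csv(tibble::as_tibble(dist), path)
  meta <- list(
    t_min = attr(dist, "t_min"), t_max = attr(dist, "t_max"),
    n_bins = attr(dist, "n_bins"), pooling = attr(dist, "pooling"),
    n_total = attr(dist, "n_total"), n_discarded = attr(dist, "n_discarded")
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_distribution
#' @export
read_distribution <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  edges <- seq(meta$t_min, meta$t_max, length.out = meta$n_bins + 1)
  attr(d, "bin_edges") <- edges
  attr(d, "bin_width") <- (meta$t_max - meta$t_min) / meta$n_bins
  attr(d, "n_total") <- meta$n_total
  attr(d, "n_discarded") <- meta$n_discarded
  attr(d, "t_min") <- meta$t_min
  attr(d, "t_max") <- meta$t_max
  attr(d, "n_bins") <- as.integer(meta$n_bins)
  attr(d, "pooling") <- meta$pooling
  class(d) <- c("interval_distribution", class(d))
  d
}

#' Plot an empirical interval distribution
#'
#' @param object An `interval_distribution`.
#' @param log_y Plot the probability axis on a log10 scale (drops empty
#'   bins).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.interval_distribution <- function(object, log_y = FALSE, ...) {
  d <- tibble::as_tibble(object)
  if (log_y) d <- dplyr::filter(d, .data$probability > 0)
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$bin_center, .data$probability)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::labs(
      x = "Inter-event interval (ms)",
      y = "Relative frequency"
    ) +
    ggplot2::theme_minimal()
  if ("channel" %in% names(d)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$channel))
  }
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}
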