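## Bounded multi-start least-squares fitting of the q-exponential model and
## its Boltzmann-Gibbs null to an empirical interval distribution.
##
## The free parameters are (b, c, h, q); the normalization a is always slaved
## analytically to them, which enforces unit area and removes one optimizer
## dimension. The 4-parameter surface has near-degenerate (b, h, q)
## directions, so single starts are unreliable: starts are drawn by Latin
## hypercube over the box, the best local solution is kept and polished.

default_fit_bounds <- function() {
  list(
    b = c(1e-6, 10),
    c = c(-0.99, 10),
    h = c(0.1, 5)
    # q has no fixed box: normalizability requires q < 1 + h/(c+1), so q is
    # parameterized as q = 1 + s * h/(c+1), s in (0, 1)
  )
}

## Internal parameterization: theta = (log b, c, log h, logit s).
## The s-map keeps every iterate inside the normalizable region.
.s_eps <- 1e-6

theta_to_qexp <- function(theta) {
  b <- exp(theta[1])
  c <- theta[2]
  h <- exp(theta[3])
  s <- plogis(theta[4])
  q <- 1 + s * h / (c + 1)
  list(b = b, c = c, h = h, q = q)
}

qexp_to_theta <- function(b, c, h, q) {
  s <- (q - 1) * (c + 1) / h
  c(log(b), c, log(h), qlogis(min(max(s, .s_eps), 1 - .s_eps)))
}

theta_bounds <- function(bounds, n_par) {
  lower <- c(log(bounds$b[1]), bounds$c[1], log(bounds$h[1]), qlogis(.s_eps))
  upper <- c(
    log(bounds$b[2]), bounds$c[2], log(bounds$h[2]),
    qlogis(1 - .s_eps)
  )
  list(lower = lower[seq_len(n_par)], upper = upper[seq_len(n_par)])
}

model_bin_prob <- function(theta, centers, width, model) {
  if (model == "qexp") {
    pr <- theta_to_qexp(theta)
    r <- (pr$c + 1) / pr$h
    la <- log(pr$h) + r * log((pr$q - 1) * pr$b) -
      lbeta(r, 1 / (pr$q - 1) - r)
    width * exp(
      la + pr$c * log(centers) -
        log1p((pr$q - 1) * pr$b * centers^pr$h) / (pr$q - 1)
    )
  } else {
    b <- exp(theta[1]); c <- theta[2]; h <- exp(theta[3])
    r <- (c + 1) / h
    la <- log(h) + r * log(b) - lgamma(r)
    width * exp(la + c * log(centers) - b * centers^h)
  }
}

fit_objective <- function(p, centers, width, model, loss) {
  if (loss == "log") {
    keep <- p > 0
    lp <- log(p[keep])
    ck <- centers[keep]
    function(theta) {
      m <- model_bin_prob(theta, ck, width, model)
      v <- sum((lp - log(m))^2)
      if (!is.finite(v)) 1e12 else v
    }
  } else {
    function(theta) {
      m <- model_bin_prob(theta, centers, width, model)
      v <- sum((p - m)^2)
      if (!is.finite(v)) 1e12 else v
    }
  }
}

run_multistart <- function(obj, bounds, n_par, n_starts, seed, extra_starts) {
  tb <- theta_bounds(bounds, n_par)
  starts <- withr::with_seed(seed, {
    u <- lhs::randomLHS(n_starts, n_par)
    sweep(sweep(u, 2, tb$upper - tb$lower, "*"), 2, tb$lower, "+")
  })
  starts <- rbind(starts, extra_starts)
  sols <- purrr::map(seq_len(nrow(starts)), function(i) {
    th0 <- pmin(pmax(starts[i, ], tb$lower), tb$upper)
    res <- tryCatch(
      optim(th0, obj,
        method = "L-BFGS-B", lower = tb$lower, upper = tb$upper,
        control = list(maxit = 500, factr = 1e7)
      ),
      error = function(e) NULL
    )
    res
  })
  sols <- sols[!vapply(sols, is.null, logical(1))]
  if (length(sols) == 0) {
    abort("No optimization start converged; the distribution may be degenerate.")
  }
  best <- sols[[which.min(vapply(sols, `[[`, numeric(1), "value"))]]
  # polish: high-precision bounded quasi-Newton, then simplex for the
  # near-degenerate directions finite differences miss
  pol <- tryCatch(
    optim(best$par, obj,
      method = "L-BFGS-B", lower = tb$lower, upper = tb$upper,
      control = list(maxit = 2000, factr = 10)
    ),
    error = function(e) best
  )
  if (pol$value <= best$value) best <- pol
  nm <- optim(best$par, function(th) {
    th <- pmin(pmax(th, tb$lower), tb$upper)
    obj(th)
  }, method = "Nelder-Mead", control = list(maxit = 4000, reltol = 1e-15))
  if (nm$value < best$value) {
    best <- list(
      par = pmin(pmax(nm$par, tb$lower), tb$upper),
      value = nm$value, convergence = nm$convergence
    )
  }
  n_conv <- sum(vapply(sols, `[[`, numeric(1), "convergence") == 0)
  list(best = best, n_converged = n_conv, n_starts = length(sols))
}

dist_vectors <- function(dist, center_offset = 0) {
  if ("channel" %in% names(dist)) {
    abort(paste(
      "Fit one distribution at a time: this per-channel distribution has a",
      "`channel` column. Split it (e.g. dplyr::group_split) or rebuild with",
      "pooling = 'pooled'."
    ))
  }
  width <- attr(dist, "bin_width")
  list(
    p = dist$probability,
    # evaluation abscissa: bin center plus any quantization alignment;
    # clamped away from 0 so a c < 0 pole cannot blow up the midpoint rule
    centers = pmax(dist$bin_center + center_offset, width / 100),
    width = width
  )
}

new_fit <- function(model, theta, value, info, dv, dist, config) {
  if (model == "qexp") {
    pr <- theta_to_qexp(theta)
    params <- qexp_params(pr$b, pr$c, pr$h, pr$q)
  } else {
    b <- exp(theta[1]); c <- theta[2]; h <- exp(theta[3])
    params <- bg_params(b, c, h)
  }
  fitted <- model_bin_prob(theta, dv$centers, dv$width, model)
  sse <- sum((dv$p - fitted)^2)
  sst <- sum((dv$p - mean(dv$p))^2)
  out <- list(
    model = model,
    params = params,
    sse = sse,
    r2 = if (sst > 0) 1 - sse / sst else NA_real_,
    loss_value = value,
    n_bins_used = length(dv$p),
    n_nonzero_bins = sum(dv$p > 0),
    converged = info$n_converged > 0,
    n_starts_converged = info$n_converged,
    fitted = fitted,
    data = dist,
    config = config
  )
  class(out) <- c(paste0(model, "_fit"), "neuroq_fit")
  out
}

#' Fit the q-exponential model to an interval distribution
#'
#' Minimizes the sum of squared differences between empirical per-bin
#' probabilities and the model probabilities (bin width x density at the
#' bin center) over `(b, c, h, q)`, with the normalization `a` slaved
#' analytically via [normalize_qexp()]. The entropic index `q` of the best
#' fit is the complexity estimate; `q -> 1` indicates dynamics compatible
#' with the uncorrelated Boltzmann-Gibbs null.
#'
#' Optimization is bounded multi-start (Latin hypercube over the parameter
#' box, seeded and therefore fully reproducible) followed by a local
#' polish. `q` is constrained to the normalizable region
#' `1 < q < 1 + h/(c+1)` by construction.
#'
#' @param dist An `interval_distribution` (pooled, or a single channel's).
#' @param n_starts Number of multi-start draws (default 32).
#' @param seed Integer seed making the start set reproducible (default 1).
#' @param bounds Named list of `(lower, upper)` for `b`, `c`, `h`;
#'   defaults to `b` in \[1e-6, 10\], `c` in \[-0.99, 10\], `h` in
#'   \[0.1, 5\].
#' @param loss `"linear"` (least squares on raw probabilities, default) or
#'   `"log"` (squared log-probability error; emphasizes the tail, drops
#'   empty bins).
#' @param include_zero_bins Keep empty bins in the linear loss (default
#'   TRUE; they penalize misplaced mass).
#' @param center_offset Abscissa alignment in ms added to bin centers when
#'   evaluating the model (default 0). When intervals are quantized to a
#'   sampling grid with period `delta` ms, a histogram bin starting at an
#'   integer edge collects the continuous-law mass of
#'   `[edge - delta/2, edge + width - delta/2)`, whose midpoint is
#'   `center - delta/2`; passing `-delta/2` removes that systematic
#'   half-sample misalignment. Leave 0 for unquantized data.
#' @return A `qexp_fit` object (also class `neuroq_fit`) with elements
#'   `params`, `sse`, `r2`, `n_bins_used`, `converged`, `model`; supports
#'   [tidy()], [glance()], [autoplot()], `print()`.
#' @examples
#' d <- model_distribution(qexp_params(0.14, 2.24, 1.07, 1.22))
#' fit <- fit_qexp(d, n_starts = 8)
#' glance(fit)
#' @seealso [fit_bg()], [compare_models()]
#' @export
fit_qexp <- function(dist, n_starts = 32, seed = 1, bounds = NULL,
                     loss = c("linear", "log"), include_zero_bins = TRUE,
                     center_offset = 0) {
  loss <- match.arg(loss)
  bounds <- utils::modifyList(default_fit_bounds(), bounds %||% list())
  dv <- dist_vectors(dist, center_offset)
  if (!include_zero_bins && loss == "linear") {
    keep <- dv$p > 0
    dv$p <- dv$p[keep]
    dv$centers <- dv$centers[keep]
  }
  if (sum(dv$p > 0) < 8) {
    abort("Need at least 8 nonzero bins to fit 4 free parameters.")
  }
  obj <- fit_objective(dv$p, dv$centers, dv$width, "qexp", loss)
  extra <- moment_start_qexp(dv, bounds)
  info <- run_multistart(obj, bounds, 4L, n_starts, seed, extra)
  config <- list(
    model = "qexp", n_starts = n_starts, seed = seed, bounds = bounds,
    loss = loss, include_zero_bins = include_zero_bins,
    center_offset = center_offset
  )
  new_fit("qexp", info$best$par, info$best$value, info, dv, dist, config)
}

#' Fit the Boltzmann-Gibbs null model
#'
#' Same contract as [fit_qexp()] for the stretched-exponential null
#' `a x^c exp(-b x^h)`, with `a` slaved via [normalize_bg()]. Used as the
#' model a purely chaotic, uncorrelated process would follow.
#'
#' @inheritParams fit_qexp
#' @return A `bg_fit` object (also class `neuroq_fit`).
#' @export
fit_bg <- function(dist, n_starts = 32, seed = 1, bounds = NULL,
                   loss = c("linear", "log"), include_zero_bins = TRUE,
                   center_offset = 0) {
  loss <- match.arg(loss)
  bounds <- utils::modifyList(default_fit_bounds(), bounds %||% list())
  dv <- dist_vectors(dist, center_offset)
  if (!include_zero_bins && loss == "linear") {
    keep <- dv$p > 0
    dv$p <- dv$p[keep]
    dv$centers <- dv$centers[keep]
  }
  if (sum(dv$p > 0) < 6) {
    abort("Need at least 6 nonzero bins to fit 3 free parameters.")
  }
  obj <- fit_objective(dv$p, dv$centers, dv$width, "bg", loss)
  extra <- moment_start_bg(dv, bounds)
  info <- run_multistart(obj, bounds, 3L, n_starts, seed, extra)
  config <- list(
    model = "bg", n_starts = n_starts, seed = seed, bounds = bounds,
    loss = loss, include_zero_bins = include_zero_bins,
    center_offset = center_offset
  )
  new_fit("bg", info$best$par, info$best$value, info, dv, dist, config)
}

## Moment-matched extra starts: a gamma-density approximation
## (h = 1, b = mean/var, c = mean^2/var - 1) plus mid-box defaults.
moment_start_qexp <- function(dv, bounds) {
  w <- pmax(dv$p, 0)
  if (sum(w) <= 0) return(NULL)
  m1 <- sum(w * dv$centers) / sum(w)
  m2 <- sum(w * dv$centers^2) / sum(w)
  v <- max(m2 - m1^2, 1e-12)
  b0 <- min(max(m1 / v, bounds$b[1] * 2), bounds$b[2] / 2)
  c0 <- min(max(m1^2 / v - 1, bounds$c[1] + 0.1), bounds$c[2] - 0.1)
  rbind(
    qexp_to_theta(b0, c0, 1, 1 + 0.1 / (c0 + 1)),
    qexp_to_theta(b0, c0, 1, 1 + 0.5 / (c0 + 1))
  )
}

moment_start_bg <- function(dv, bounds) {
  th <- moment_start_qexp(dv, bounds)
  if (is.null(th)) NULL else th[, 1:3, drop = FALSE]
}

#' Fit both models and compare them
#'
#' Fits the q-exponential model and the Boltzmann-Gibbs null to the same
#' distribution (identical bins and loss) and reports which attains the
#' smaller sum of squared errors. Because the q-exponential family nests
#' the null at its `q -> 1` boundary, its SSE can never be meaningfully
#' larger; a near-zero `delta_sse` indicates data compatible with the
#' uncorrelated null.
#'
#' @inheritParams fit_qexp
#' @return A `model_comparison` list with elements `qexp`, `bg`
#'   (both `neuroq_fit`), `delta_sse` (`bg$sse - qexp$sse`) and `preferred`.
#' @examples
#' d <- model_distribution(qexp_params(0.14, 2.24, 1.07, 1.22))
#' cmp <- compare_models(d, n_starts = 8)
#' cmp$preferred
#' @export
compare_models <- function(dist, n_starts = 32, seed = 1, bounds = NULL,
                           loss = c("linear", "log"),
                           include_zero_bins = TRUE, center_offset = 0) {
  loss <- match.arg(loss)
  fq <- fit_qexp(dist, n_starts, seed, bounds, loss, include_zero_bins,
    center_offset)
  fb <- fit_bg(dist, n_starts, seed, bounds, loss, include_zero_bins,
    center_offset)
  out <- list(
    qexp = fq,
    bg = fb,
    delta_sse = fb$sse - fq$sse,
    preferred = if (fq$sse < fb$sse) "qexp" else "bg"
  )
  class(out) <- "model_comparison"
  out
}

#' @export
print.neuroq_fit <- function(x, ...) {
  cat(sprintf(
    "<%s_fit>  sse = %.4g  r2 = %.5f  bins = %d  converged = %s\n",
    x$model, x$sse, x$r2, x$n_bins_used, x$converged
  ))
  print(tidy(x))
  invisible(x)
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf(
    "<model_comparison>  preferred = %s  delta_sse = %.4g\n",
    x$preferred, x$delta_sse
  ))
  cat(sprintf("  qexp: q = %.4f, sse = %.4g\n", x$qexp$params$q, x$qexp$sse))
  cat(sprintf("  bg:   sse = %.4g\n", x$bg$sse))
  invisible(x)
}

#' Tidy a fitted interval-distribution model
#'
#' @param x A `neuroq_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`term`, `estimate`).
#' @exportS3Method generics::tidy
tidy.neuroq_fit <- function(x, ...) {
  p <- x$params
  terms <- if (x$model == "qexp") c("a", "b", "c", "h", "q") else c("a", "b", "c", "h")
  tibble::tibble(
    term = terms,
    estimate = as.numeric(p[1, terms])
  )
}

#' One-row fit summary
#'
#' @param x A `neuroq_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `model`, `q`, `sse`, `r2`, `n_bins_used`,
#'   `converged`.
#' @exportS3Method generics::glance
glance.neuroq_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model,
    q = if (x$model == "qexp") x$params$q else 1,
    sse = x$sse,
    r2 = x$r2,
    n_bins_used = x$n_bins_used,
    converged = x$converged
  )
}

#' Plot a fit over its empirical distribution
#'
#' @param object A `neuroq_fit`.
#' @param log_y Log10 probability axis (drops empty bins).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.neuroq_fit <- function(object, log_y = FALSE, ...) {
  d <- tibble::tibble(
    bin_center = object$data$bin_center,
    probability = object$data$probability
  )
  centers <- object$data$bin_center
  width <- attr(object$data, "bin_width")
  grid <- seq(min(centers), max(centers), length.out = 512)
  dens <- if (object$model == "qexp") {
    qexp_pdf(grid, object$params)
  } else {
    bg_pdf(grid, object$params)
  }
  line <- tibble::tibble(bin_center = grid, probability = width * dens)
  if (log_y) {
    d <- dplyr::filter(d, .data$probability > 0)
    line <- dplyr::filter(line, .data$probability > 0)
  }
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$bin_center, .data$probability)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.6) +
    ggplot2::geom_line(data = line, colour = "red") +
    ggplot2::labs(
      x = "Inter-event interval (ms)", y = "Relative frequency",
      title = sprintf(
        "%s fit%s", object$model,
        if (object$model == "qexp") sprintf(" (q = %.3f)", object$params$q) else ""
      )
    ) +
    ggplot2::theme_minimal()
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' Serialize a fit or model comparison to JSON
#'
#' Writes parameters, goodness of fit, the full fitting configuration
#' (bounds, seed, loss, start count) and the package version, so a run can
#' be reproduced from its output alone.
#'
#' @param x A `neuroq_fit` or `model_comparison`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(x, path) {
  jsonlite::write_json(fit_to_list(x), path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

fit_to_list <- function(x) {
  if (inherits(x, "model_comparison")) {
    return(list(
      type = "model_comparison",
      preferred = x$preferred,
      delta_sse = x$delta_sse,
      qexp = fit_to_list(x$qexp),
      bg = fit_to_list(x$bg)
    ))
  }
  list(
    type = paste0(x$model, "_fit"),
    params = as.list(tibble::as_tibble(x$params)[1, ]),
    sse = x$sse,
    r2 = x$r2,
    n_bins_used = x$n_bins_used,
    converged = x$converged,
    config = x$config,
    histogram = list(
      n_bins = attr(x$data, "n_bins"),
      t_min = attr(x$data, "t_min"),
      t_max = attr(x$data, "t_max"),
      n_total = attr(x$data, "n_total"),
      n_discarded = attr(x$data, "n_discarded")
    ),
    package_version = as.character(utils::packageVersion("neuroq"))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
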