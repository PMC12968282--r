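test_that("noiseless worked-example distribution is recovered essentially exactly", {
  truth <- qexp_params(0.14, 2.24, 1.07, 1.22)
  d <- model_distribution(truth, n_bins = 500)
  fit <- fit_qexp(d, n_starts = 16, seed = 1)
  expect_true(fit$converged)
  expect_equal(fit$params$q, 1.22, tolerance = 1e-3)
  expect_equal(fit$params$c, 2.24, tolerance = 1e-3)
  expect_equal(fit$params$h, 1.07, tolerance = 1e-3)
  expect_equal(fit$params$b, 0.14, tolerance = 1e-3)
  expect_lt(fit$sse, 1e-15)
  expect_gt(fit$r2, 1 - 1e-10)
})

test_that("Boltzmann-Gibbs null round-trips noiselessly", {
  d <- model_distribution(bg_params(1, 0, 1), n_bins = 500)
  fit <- fit_bg(d, n_starts = 16, seed = 2)
  expect_equal(fit$params$b, 1, tolerance = 1e-3)
  expect_equal(fit$params$c, 0, tolerance = 1e-3)
  expect_equal(fit$params$h, 1, tolerance = 1e-3)
  expect_lt(fit$sse, 1e-10)
})

test_that("fitting BG-generated data pins q at its lower bound", {
  d <- model_distribution(bg_params(0.5, 1, 1), n_bins = 500)
  cmp <- compare_models(d, n_starts = 16, seed = 3)
  expect_lt(cmp$qexp$params$q, 1.01)
  expect_lt(abs(cmp$delta_sse), 1e-8)
})

test_that("heavy-tailed data defeat the nested null", {
  truth <- qexp_params(0.05, 0.5, 1.2, 1.6)
  d <- model_distribution(truth, n_bins = 500)
  cmp <- compare_models(d, n_starts = 16, seed = 4)
  expect_identical(cmp$preferred, "qexp")
  expect_gt(cmp$bg$sse, cmp$qexp$sse)
  expect_gt(cmp$delta_sse, 0)
})

test_that("the q-exponential family never fits worse than its q -> 1 boundary", {
  cases <- c(
    draw_qexp_params(4, seed = 6),
    list(bg_params(0.3, 1.5, 1), bg_params(1, 0, 1))
  )
  for (pp in cases) {
    d <- model_distribution(pp, n_bins = 200)
    fq <- fit_qexp(d, n_starts = 8, seed = 5)
    fb <- fit_bg(d, n_starts = 8, seed = 5)
    expect_lte(fq$sse, fb$sse + 1e-10)
  }
})

test_that("identical input and seed give bit-identical results", {
  withr::with_seed(10, {
    iv <- 1000 * rbeta(4000, 1.3, 5)
  })
  d <- bin_intervals(iv, n_bins = 500)
  c1 <- compare_models(d, n_starts = 8, seed = 123)
  c2 <- compare_models(d, n_starts = 8, seed = 123)
  expect_identical(c1$qexp$params, c2$qexp$params)
  expect_identical(c1$bg$params, c2$bg$params)
  expect_identical(c1$qexp$sse, c2$qexp$sse)
  expect_identical(c1$preferred, c2$preferred)
})

test_that("noiseless round trips recover parameters across the q range", {
  # shapes across 1.05 <= q <= 1.8 with EEG-scale means
  draws <- withr::with_seed(42, {
    out <- list()
    while (length(out) < 20) {
      c0 <- runif(1, 0, 3)
      h0 <- runif(1, 0.8, 2.5)
      s0 <- runif(1, 0.15, 0.85)
      q0 <- 1 + s0 * h0 / (c0 + 1)
      if (q0 < 1.05 || q0 > 1.8) next
      target_mean <- exp(runif(1, log(30), log(200)))
      f <- function(lb) {
        p <- qexp_params(exp(lb), c0, h0, q0)
        m <- tryCatch(
          integrate(function(x) x * qexp_pdf(x, p), 0, Inf,
            rel.tol = 1e-7, subdivisions = 800L
          )$value,
          error = function(e) NA_real_
        )
        if (is.na(m)) return(NA_real_) else m - target_mean
      }
      lb <- tryCatch(
        suppressWarnings(uniroot(f, c(-25, 3), tol = 1e-9)$root),
        error = function(e) NA_real_
      )
      if (is.na(lb)) next
      # keep the truth well inside the fitter's default parameter box
      if (exp(lb) < 1e-5 || exp(lb) > 5) next
      out[[length(out) + 1]] <- qexp_params(exp(lb), c0, h0, q0)
    }
    out
  })
  for (truth in draws) {
    d <- model_distribution(truth, n_bins = 500)
    fit <- fit_qexp(d, n_starts = 16, seed = 7)
    expect_lt(abs(fit$params$q - truth$q), 0.01)
    expect_lt(abs(fit$params$b - truth$b) / truth$b, 0.05)
    expect_lt(abs(fit$params$h - truth$h) / truth$h, 0.05)
    expect_lt(abs(fit$params$c - truth$c) / max(abs(truth$c), 0.2), 0.05)
  }
})

test_that("sampled-interval fits at the pooled study scale stay near truth", {
  truth <- surrogate_conditions()[["1.22"]]
  for (s in 1:3) {
    iv <- unlist(lapply(1:20, function(ch) {
      sample_qexp_intervals(truth, 1e4, seed = s * 100 + ch)
    }))
    fit <- fit_qexp(bin_intervals(iv), n_starts = 8, seed = 1)
    expect_lt(abs(fit$params$q - truth$q), 0.05)
  }
})

test_that("insufficient support is an explicit error", {
  d <- bin_intervals(rep(c(10, 30, 50), 100), n_bins = 100)
  expect_error(fit_qexp(d), "8 nonzero")
  expect_error(fit_bg(bin_intervals(rep(10, 50), n_bins = 100)), "6 nonzero")
  per <- bin_intervals(
    tibble::tibble(channel = rep(c("a", "b"), 50), interval_ms = runif(100, 0, 900)),
    pooling = "per_channel"
  )
  expect_error(fit_qexp(per), "one distribution at a time")
})

test_that("tidy, glance, plot and JSON serialization work on fits", {
  truth <- qexp_params(0.14, 2.24, 1.07, 1.22)
  d <- model_distribution(truth, n_bins = 200)
  fit <- fit_qexp(d, n_starts = 8, seed = 1)
  td <- tidy(fit)
  expect_equal(td$term, c("a", "b", "c", "h", "q"))
  gl <- glance(fit)
  expect_equal(gl$model, "qexp")
  expect_true(gl$converged)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(autoplot(fit, log_y = TRUE), "ggplot")
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_json(fit, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$params$q, fit$params$q, tolerance = 1e-12)
  expect_equal(back$config$seed, 1)
  expect_equal(back$histogram$n_bins, 200)
})

test_that("quantization alignment shifts the evaluation abscissa as derived", {
  # integer-valued intervals on 2 ms bins: model evaluated at center - 0.5
  truth <- qexp_params(0.14, 2.24, 1.07, 1.22)
  iv <- round(sample_qexp_intervals(truth, 5e4, seed = 31))
  d <- bin_intervals(iv)
  f0 <- fit_qexp(d, n_starts = 8, seed = 1)
  f5 <- fit_qexp(d, n_starts = 8, seed = 1, center_offset = -0.5)
  # the aligned fit must describe the quantized data at least as well
  expect_lte(f5$loss_value, f0$loss_value * 1.05)
  expect_equal(f5$config$center_offset, -0.5)
})
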