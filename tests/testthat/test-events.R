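test_that("negative-part statistics use only samples below zero, population SD", {
  expect_equal(
    negative_part_stats(c(-1, -1, 5, 10)),
    tibble::tibble(mean_neg = -1, sd_neg = 0, n_neg = 2L)
  )
  # 997 samples at -1 and 3 at -10, positives ignored:
  # mean = -1027/1000, var = (997 + 300)/1000 - mean^2
  x <- c(rep(-1, 997), rep(-10, 3), runif(50, 1, 2))
  st <- negative_part_stats(x)
  expect_equal(st$mean_neg, -1.027, tolerance = 1e-12)
  expect_equal(st$sd_neg, sqrt(1.297 - 1.027^2), tolerance = 1e-12)
  expect_equal(st$sd_neg, 0.4922, tolerance = 1e-4)
  expect_error(negative_part_stats(c(1, 2, 3)), "negative")
  expect_error(negative_part_stats(c(-1, 2, 3)), "negative")
})

test_that("events are maximal sub-threshold runs stamped at the crossing", {
  x <- rep(-1, 1000)
  x[c(101, 301, 601)] <- -10 # 0-based samples 100, 300, 600
  sig <- eeg_signal(x, fs = 1000)
  ev <- detect_events(sig)
  expect_equal(ev$event_time_ms, c(100, 300, 600))
  expect_equal(unique(ev$threshold), -1.027 - sqrt(1.297 - 1.027^2),
    tolerance = 1e-12
  )
  # constant channel: sd_neg = 0, nothing below the threshold
  flat <- eeg_signal(rep(-2, 100), fs = 100)
  expect_equal(nrow(detect_events(flat)), 0)
  # one contiguous 5-sample excursion is a single event
  y <- rep(-1, 500)
  y[201:205] <- -30
  ev1 <- detect_events(eeg_signal(y, fs = 1000))
  expect_equal(nrow(ev1), 1)
  expect_equal(ev1$event_time_ms, 200)
  # the "minimum" convention stamps the most negative sample of the run
  y2 <- rep(-1, 500)
  y2[201:205] <- c(-20, -25, -40, -25, -20)
  ev2 <- detect_events(eeg_signal(y2, fs = 1000), event_time = "minimum")
  expect_equal(ev2$event_time_ms, 202)
})

test_that("unusable channels are skipped with a warning, others proceed", {
  sig <- eeg_signal(
    cbind(good = {
      z <- rep(-1, 300)
      z[c(51, 151)] <- -10
      z
    }, dead = rep(2, 300)),
    fs = 1000
  )
  expect_warning(ev <- detect_events(sig), "dead")
  expect_equal(attr(ev, "skipped"), "dead")
  expect_equal(ev$event_time_ms, c(50, 150))
})

test_that("planted events are recovered exactly and detection is scale-invariant", {
  withr::with_seed(21, {
    n <- 5000
    planted <- sort(sample(10:(n - 10), 40))
    planted <- planted[c(TRUE, diff(planted) > 1)] # separated by > 1 sample
    x <- rnorm(n, mean = -1, sd = 0.5)
    x[planted + 1] <- -30 # index planted 0-based times
    sig <- eeg_signal(x, fs = 1000)
    ev <- detect_events(sig)
    expect_equal(ev$event_time_ms, planted)
    # positive rescaling changes nothing
    ev2 <- detect_events(eeg_signal(17.3 * x, fs = 1000))
    expect_equal(ev2$event_time_ms, ev$event_time_ms)
  })
})

test_that("deeper thresholds never yield more events", {
  withr::with_seed(5, {
    x <- rnorm(20000, mean = 0, sd = 1)
    sig <- eeg_signal(x, fs = 1000)
    counts <- vapply(
      c(0.5, 1, 1.5, 2, 3),
      function(k) nrow(detect_events(sig, n_sd = k)),
      integer(1)
    )
    expect_true(all(diff(counts) <= 0))
    expect_gt(counts[1], 0)
  })
})

test_that("intervals are successive differences and conserve the total span", {
  ev <- tibble::tibble(channel = "a", event_time_ms = c(100, 300, 600))
  iv <- event_intervals(ev)
  expect_equal(iv$interval_ms, c(200, 300))
  expect_equal(sum(iv$interval_ms), 600 - 100)
  # fewer than two events: empty series
  expect_equal(
    nrow(event_intervals(tibble::tibble(
      channel = "a", event_time_ms = 42
    ))),
    0
  )
  expect_equal(
    nrow(event_intervals(tibble::tibble(
      channel = character(0), event_time_ms = numeric(0)
    ))),
    0
  )
  # conservation on detected trains, per channel
  withr::with_seed(9, {
    x <- rnorm(30000, -0.5, 1)
    ev <- detect_events(eeg_signal(cbind(a = x, b = rev(x)), fs = 500))
    iv <- event_intervals(ev)
    spans <- ev |>
      dplyr::group_by(channel) |>
      dplyr::summarise(span = max(event_time_ms) - min(event_time_ms))
    sums <- iv |>
      dplyr::group_by(channel) |>
      dplyr::summarise(total = sum(interval_ms))
    expect_equal(sums$total, spans$span)
  })
})
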