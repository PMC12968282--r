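test_that("Boltzmann-Gibbs entropy matches closed forms and hand sums", {
  expect_equal(entropy_bg(c(1, 0, 0))$value, 0)
  expect_equal(entropy_bg(rep(0.25, 4))$value, log(4), tolerance = 1e-12)
  # direct summation: -(0.5 log 0.5 + 2 * 0.25 log 0.25)
  expect_equal(entropy_bg(c(0.5, 0.25, 0.25))$value,
    -(0.5 * log(0.5) + 0.5 * log(0.25)),
    tolerance = 1e-12
  )
  expect_equal(entropy_bg(c(0.5, 0.25, 0.25))$value, 1.039721,
    tolerance = 1e-6
  )
  expect_equal(entropy_bg(rep(0.1, 10), k = 2)$value, 2 * log(10))
})

test_that("probability vectors are validated", {
  expect_error(entropy_bg(c(0.5, 0.6)), "sum to 1")
  expect_error(entropy_bg(c(-0.1, 1.1)), "non-negative")
  expect_error(entropy_bg(numeric(0)), "non-empty")
  expect_error(entropy_tsallis(c(0.3, 0.3), q = 2), "sum to 1")
})

test_that("Tsallis entropy: examples, q = 1 routing, equiprobable closed form", {
  expect_equal(entropy_tsallis(c(0.5, 0.5), q = 2)$value, 0.5)
  expect_equal(entropy_tsallis(c(1, 0), q = 1.7)$value, 0)
  # q = 1 must go through the analytic limit, never divide by zero
  expect_identical(
    entropy_tsallis(c(0.5, 0.25, 0.25), q = 1)$value,
    entropy_bg(c(0.5, 0.25, 0.25))$value
  )
  # equiprobable closed form k (W^(1-q) - 1)/(1-q), the q-logarithm of W
  for (W in c(2, 5, 16)) {
    for (q in c(1.2, 1.5, 2.5)) {
      expect_equal(
        entropy_tsallis(rep(1 / W, W), q = q)$value,
        (W^(1 - q) - 1) / (1 - q),
        tolerance = 1e-12
      )
    }
  }
})

test_that("Tsallis entropy converges to Boltzmann-Gibbs as q -> 1", {
  withr::with_seed(7, {
    for (i in 1:20) {
      p <- runif(sample(2:12, 1))
      p <- p / sum(p)
      expect_lt(
        abs(entropy_tsallis(p, q = 1 + 1e-8)$value - entropy_bg(p)$value),
        1e-5
      )
    }
  })
})

test_that("Tsallis entropy is non-negative and maximal at equiprobability", {
  withr::with_seed(11, {
    for (q in c(1.1, 1.5, 2)) {
      W <- 6
      uniform <- entropy_tsallis(rep(1 / W, W), q = q)$value
      for (i in 1:25) {
        p <- runif(W)
        p <- p / sum(p)
        s <- entropy_tsallis(p, q = q)$value
        expect_gte(s, 0)
        expect_lte(s, uniform + 1e-12)
      }
    }
  })
})

test_that("q-exponential density: boundary values and closed-form arithmetic", {
  p <- qexp_params(b = 1, c = 2, h = 1, q = 1.2)
  expect_equal(qexp_pdf(0, p), 0) # x^c factor vanishes for c > 0
  # fixed a: 0.5 * (1 + 0.5 * 2)^(-2) = 0.125
  manual <- list(a = 0.5, b = 1, c = 0, h = 1, q = 1.5)
  expect_equal(qexp_pdf(2, manual), 0.125, tolerance = 1e-12)
  expect_error(qexp_pdf(-1, p), "non-negative")
  expect_error(qexp_params(b = -1, c = 0, h = 1, q = 1.5), "`b`")
  expect_error(qexp_params(b = 1, c = 0, h = 1, q = 0.9), "`q`")
})

test_that("Boltzmann-Gibbs density: unit exponential and boundaries", {
  expect_equal(bg_pdf(1, bg_params(1, 0, 1)), exp(-1), tolerance = 1e-12)
  expect_equal(bg_pdf(0, bg_params(1, 0.5, 1)), 0)
  expect_error(bg_params(b = 0, c = 0, h = 1), "`b`")
})

test_that("q-exponential reduces to the Boltzmann-Gibbs model as q -> 1", {
  x <- seq(0, 100, length.out = 512)
  for (pars in list(c(1, 0, 1), c(0.14, 2.24, 1.07), c(0.5, 1, 0.8))) {
    bg <- bg_params(pars[1], pars[2], pars[3])
    near1 <- list(a = bg$a, b = pars[1], c = pars[2], h = pars[3], q = 1 + 1e-9)
    expect_lt(max(abs(qexp_pdf(x, near1) - bg_pdf(x, bg))), 1e-5)
  }
})

test_that("analytic normalization matches quadrature", {
  # exact case: integral of (1 + 0.5 x)^(-2) is 2, so a = 0.5
  expect_equal(normalize_qexp(b = 1, c = 0, h = 1, q = 1.5), 0.5,
    tolerance = 1e-12
  )
  # worked-example parameters: unit area under quadrature
  p <- qexp_params(0.14, 2.24, 1.07, 1.22)
  I <- integrate(function(x) qexp_pdf(x, p), 0, Inf, rel.tol = 1e-10)
  expect_lt(abs(I$value - 1), 1e-6)
  # random draws: unit area everywhere in the normalizable region
  for (pp in draw_qexp_params(40, seed = 3)) {
    I <- integrate(function(x) qexp_pdf(x, pp), 0, Inf,
      rel.tol = 1e-9, subdivisions = 1000L
    )
    expect_lt(abs(I$value - 1), 1e-6)
  }
})

test_that("normalization violation raises a named error", {
  expect_error(
    normalize_qexp(b = 1, c = 3, h = 1, q = 1.5),
    "1/\\(q-1\\) > \\(c\\+1\\)/h"
  )
})

test_that("q -> 1 limit of the normalization is the Boltzmann-Gibbs constant", {
  for (pars in list(c(1, 0, 1), c(0.14, 2.24, 1.07), c(2, 0.5, 1))) {
    a_bg <- normalize_bg(pars[1], pars[2], pars[3])
    a_q <- normalize_qexp(pars[1], pars[2], pars[3], q = 1 + 1e-9)
    expect_equal(a_q, a_bg, tolerance = 1e-6)
  }
  # and the BG constant itself against quadrature
  a <- normalize_bg(b = 2, c = 0.5, h = 1)
  expect_equal(a, 2^1.5 / gamma(1.5), tolerance = 1e-12)
  I <- integrate(function(x) bg_pdf(x, bg_params(2, 0.5, 1)), 0, Inf,
    rel.tol = 1e-10
  )
  expect_lt(abs(I$value - 1), 1e-8)
  expect_equal(normalize_bg(1, 0, 1), 1)
  expect_equal(normalize_bg(1, 1, 1), 1) # Gamma(2) = 1
})
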