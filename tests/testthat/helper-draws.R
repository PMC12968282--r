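# Random valid q-exponential parameter draws used by property-style tests.
# Shapes are kept in the EEG-plausible region and q inside the normalizable
# band 1 < q < 1 + h/(c+1) by construction.
draw_qexp_params <- function(n, seed = 1, s_range = c(0.1, 0.9)) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      c0 <- runif(1, -0.5, 4)
      h0 <- runif(1, 0.5, 3)
      b0 <- exp(runif(1, log(0.01), log(2)))
      s0 <- runif(1, s_range[1], s_range[2])
      qexp_params(b0, c0, h0, 1 + s0 * h0 / (c0 + 1))
    })
  })
}

# Quadrature CDF of a q-exponential law at given points (independent oracle).
quad_cdf <- function(params, x) {
  vapply(x, function(u) {
    stats::integrate(function(t) qexp_pdf(t, params), 0, u,
      rel.tol = 1e-10, subdivisions = 500L
    )$value
  }, numeric(1))
}
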