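## Core nonextensive-statistics math: entropy functionals, the q-exponential
## probability function and its Boltzmann-Gibbs (q -> 1) limit, and the
## analytic gamma-function normalization tying the constant a to (b, c, h, q).

#' Validate a discrete probability vector
#'
#' @param p Numeric vector of probabilities.
#' @param tol Tolerance on `sum(p) == 1`.
#' @return `p`, invisibly, after validation.
#' @keywords internal
validate_probability <- function(p, tol = 1e-9) {
  if (!is.numeric(p) || length(p) < 1L) {
    abort("`p` must be a non-empty numeric vector of probabilities.")
  }
  if (anyNA(p) || any(p < 0)) {
    abort("`p` must be non-negative and free of missing values.")
  }
  if (abs(sum(p) - 1) > tol) {
    abort(sprintf("`p` must sum to 1 (got %.12g).", sum(p)))
  }
  invisible(p)
}

#' Boltzmann-Gibbs entropy
#'
#' Computes \eqn{S_{BG} = -k \sum_i p_i \ln p_i} over a discrete probability
#' vector. Terms with \eqn{p_i = 0} contribute zero (the \eqn{p \ln p \to 0}
#' limit convention). For `W` equiprobable states this is \eqn{k \ln W}.
#'
#' @param p Probability vector (non-negative, sums to 1).
#' @param k Scale constant (Boltzmann's constant in physical units; defaults
#'   to 1 for dimensionless entropy).
#' @return A one-row tibble with columns `value`, `k`, and `q` (`q = 1`
#'   marks the Boltzmann-Gibbs limit).
#' @examples
#' entropy_bg(rep(0.25, 4)) # k * log(4)
#' @seealso [entropy_tsallis()]
#' @export
entropy_bg <- function(p, k = 1) {
  validate_probability(p)
  pos <- p[p > 0]
  tibble::tibble(value = -k * sum(pos * log(pos)), k = k, q = 1)
}

#' Tsallis entropy
#'
#' Computes the nonextensive entropy
#' \eqn{S_q = \frac{k}{q - 1}\left(1 - \sum_i p_i^q\right)}, the
#' generalization of the Boltzmann-Gibbs functional for systems with
#' long-range correlations. `q = 1` is routed through [entropy_bg()], the
#' analytic limit, so no division by zero can occur. For equiprobable
#' states the closed form \eqn{k (W^{1-q} - 1)/(1-q)} holds.
#'
#' @inheritParams entropy_bg
#' @param q Entropic index. `q = 1` recovers Boltzmann-Gibbs.
#' @return A one-row tibble with columns `value`, `k`, and `q`.
#' @examples
#' entropy_tsallis(c(0.5, 0.5), q = 2) # 0.5
#' @export
entropy_tsallis <- function(p, q, k = 1) {
  if (!is.numeric(q) || length(q) != 1L || is.na(q)) {
    abort("`q` must be a single finite number.")
  }
  if (q == 1) {
    return(entropy_bg(p, k = k))
  }
  validate_probability(p)
  pos <- p[p > 0] # 0^q contributes 0 for q > 0
  tibble::tibble(value = k / (q - 1) * (1 - sum(pos^q)), k = k, q = q)
}

#' Normalization constant of the q-exponential probability function
#'
#' The density \eqn{a x^c \left[1 + (q-1) b x^h\right]^{-1/(q-1)}} on
#' \eqn{[0, \infty)} integrates to 1 when
#' \deqn{a = \frac{h\,[(q-1)b]^{(c+1)/h}}{B\!\left(\frac{c+1}{h},\,
#'   \frac{1}{q-1} - \frac{c+1}{h}\right)},}
#' a ratio of gamma functions via the Beta function. The integral converges
#' only under the normalizability condition \eqn{1/(q-1) > (c+1)/h}; outside
#' it the function has infinite area and no valid `a` exists.
#'
#' @param b Scale parameter (> 0), in units of inverse interval^h.
#' @param c Power-law exponent of the rising prefactor (> -1).
#' @param h Stretching exponent (> 0).
#' @param q Entropic index (> 1).
#' @return The normalization constant `a` (per unit of x).
#' @examples
#' normalize_qexp(b = 1, c = 0, h = 1, q = 1.5) # 0.5
#' @export
normalize_qexp <- function(b, c, h, q) {
  check_qexp_params(b, c, h, q)
  r <- (c + 1) / h
  # log-space form of h * ((q-1) b)^r / Beta(r, 1/(q-1) - r); stable as q -> 1+
  h * exp(r * log((q - 1) * b) - lbeta(r, 1 / (q - 1) - r))
}

#' Normalization constant of the Boltzmann-Gibbs model
#'
#' The stretched-exponential density
#' \eqn{a_{BG} x^{c} e^{-b x^{h}}} integrates to 1 on \eqn{[0,\infty)} when
#' \eqn{a_{BG} = h b^{(c+1)/h} / \Gamma((c+1)/h)}. This is the `q -> 1`
#' limit of [normalize_qexp()].
#'
#' @inheritParams normalize_qexp
#' @return The normalization constant.
#' @examples
#' normalize_bg(b = 1, c = 0, h = 1) # 1: the unit exponential
#' @export
normalize_bg <- function(b, c, h) {
  check_bg_params(b, c, h)
  r <- (c + 1) / h
  h * b^r / gamma(r)
}

check_qexp_params <- function(b, c, h, q) {
  for (nm in c("b", "c", "h", "q")) {
    v <- get(nm, inherits = FALSE)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      abort(sprintf("`%s` must be a single finite number.", nm))
    }
  }
  if (b <= 0) abort("`b` must be > 0.")
  if (h <= 0) abort("`h` must be > 0.")
  if (c <= -1) abort("`c` must be > -1.")
  if (q <= 1) abort("`q` must be > 1 (use the Boltzmann-Gibbs model at q = 1).")
  if (1 / (q - 1) <= (c + 1) / h) {
    abort(sprintf(
      "Normalizability violated: need 1/(q-1) > (c+1)/h, but 1/(q-1) = %.6g <= %.6g = (c+1)/h. The density would have infinite area.",
      1 / (q - 1), (c + 1) / h
    ))
  }
  invisible(TRUE)
}

check_bg_params <- function(b, c, h) {
  for (nm in c("b", "c", "h")) {
    v <- get(nm, inherits = FALSE)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      abort(sprintf("`%s` must be a single finite number.", nm))
    }
  }
  if (b <= 0) abort("`b` must be > 0.")
  if (h <= 0) abort("`h` must be > 0.")
  if (c <= -1) abort("`c` must be > -1.")
  invisible(TRUE)
}

#' q-exponential model parameters
#'
#' Bundles the four free parameters of the q-exponential probability
#' function together with the analytically slaved normalization constant
#' `a` from [normalize_qexp()]. `a` is never free: fixing it enforces unit
#' area and removes one optimizer dimension.
#'
#' @inheritParams normalize_qexp
#' @return A one-row tibble of class `qexp_params` with columns
#'   `a`, `b`, `c`, `h`, `q`.
#' @examples
#' qexp_params(b = 0.14, c = 2.24, h = 1.07, q = 1.22)
#' @export
qexp_params <- function(b, c, h, q) {
  a <- normalize_qexp(b, c, h, q)
  out <- tibble::tibble(a = a, b = b, c = c, h = h, q = q)
  class(out) <- c("qexp_params", class(out))
  out
}

#' Boltzmann-Gibbs model parameters
#'
#' @inheritParams normalize_bg
#' @return A one-row tibble of class `bg_params` with columns
#'   `a`, `b`, `c`, `h` (and `q = 1` for reference).
#' @export
bg_params <- function(b, c, h) {
  a <- normalize_bg(b, c, h)
  out <- tibble::tibble(a = a, b = b, c = c, h = h, q = 1)
  class(out) <- c("bg_params", class(out))
  out
}

#' q-exponential probability density
#'
#' Evaluates \eqn{y(x) = a x^c \left[1 + (q-1) b x^h\right]^{-1/(q-1)}} for
#' \eqn{x \ge 0}: a power-law rise \eqn{x^c} times a decaying q-exponential
#' tail. As \eqn{q \to 1^+} the bracket converges to \eqn{e^{-b x^h}} and
#' the density reduces continuously to the Boltzmann-Gibbs model of
#' [bg_pdf()].
#'
#' @param x Non-negative evaluation points (interval values, ms).
#' @param params A [qexp_params()] object, or a list/one-row data frame with
#'   fields `b`, `c`, `h`, `q` (and optionally `a`; recomputed when absent).
#' @return Density values, same length as `x`.
#' @examples
#' p <- qexp_params(b = 0.14, c = 2.24, h = 1.07, q = 1.22)
#' qexp_pdf(c(0, 50, 500), p)
#' @export
qexp_pdf <- function(x, params) {
  pr <- as.list(params)
  check_qexp_params(pr$b, pr$c, pr$h, pr$q)
  if (is.null(pr$a)) pr$a <- normalize_qexp(pr$b, pr$c, pr$h, pr$q)
  if (any(x < 0, na.rm = TRUE)) abort("`x` must be non-negative.")
  # x^c at x = 0: 0 for c > 0, 1 for c = 0, +Inf for c < 0 (integrable pole);
  # (1 + z)^(-1/(q-1)) computed as exp(-log1p(z)/(q-1)), stable as q -> 1+
  pr$a * x^pr$c * exp(-log1p((pr$q - 1) * pr$b * x^pr$h) / (pr$q - 1))
}

#' Boltzmann-Gibbs probability density
#'
#' Evaluates \eqn{y(x) = a x^{c} e^{-b x^{h}}}, the stretched-exponential
#' null model describing a purely chaotic (uncorrelated) process; the
#' q-exponential model nests it as its \eqn{q \to 1} boundary.
#'
#' @param x Non-negative evaluation points (interval values, ms).
#' @param params A [bg_params()] object, or a list/one-row data frame with
#'   fields `b`, `c`, `h` (and optionally `a`).
#' @return Density values, same length as `x`.
#' @export
bg_pdf <- function(x, params) {
  pr <- as.list(params)
  check_bg_params(pr$b, pr$c, pr$h)
  if (is.null(pr$a)) pr$a <- normalize_bg(pr$b, pr$c, pr$h)
  if (any(x < 0, na.rm = TRUE)) abort("`x` must be non-negative.")
  pr$a * x^pr$c * exp(-pr$b * x^pr$h)
}
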