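#' Two-sided tolerance factors for normal differences
#'
#' A beta-gamma content tolerance interval has the form `D-bar +/- k S`.
#' `bg_factor_approx()` returns the explicit first-order factor
#' \deqn{k = z_{(1+\beta)/2}\,\sqrt{1 + 1/n}\,\sqrt{(n-1)/\chi^2_{1-\gamma,\,n-1}},}
#' the Student quantile of the prediction interval replaced by a normal
#' quantile and S inflated to the upper bound of its chi-square confidence
#' interval.  `bg_factor_exact()` solves the exact two-sided condition: k is
#' the root of
#' \deqn{\sqrt{2n/\pi}\int_0^\infty
#'   \Pr\!\left(\chi^2_{n-1} > \frac{(n-1)\,\chi^2_{1,\beta}(z^2)}{k^2}\right)
#'   e^{-n z^2/2}\,dz \;=\; \gamma,}
#' where \eqn{\chi^2_{1,\beta}(z^2)} is the beta-quantile of the noncentral
#' chi-square distribution with 1 degree of freedom and noncentrality
#' \eqn{z^2}.  The integral is the probability, over the sampling
#' distribution of `(D-bar, S)`, that the interval captures at least a
#' proportion beta of the population.
#'
#' @param n sample size, integer >= 2.
#' @param beta content level in (0, 1).
#' @param gamma confidence level in (0, 1).
#' @param rel_tol relative tolerance on the root k (default 1e-6; the root
#'   itself is polished well beyond this by the bracketing solver).
#' @return A `"tolerance_factor"`: list with `n`, `beta`, `gamma`, `k`,
#'   `method`.
#' @details The integrand weight `sqrt(2n/pi) exp(-n z^2 / 2)` is the
#'   half-normal density of the standardized sample mean, so the integrand
#'   is bounded by it and vanishes rapidly; integration is truncated at
#'   `z_max = 10/sqrt(n) + 8`, beyond which the weight's tail mass is below
#'   1e-12.  The root is bracketed around the approximate factor
#'   (`[0.8, 1.3]` times it, widened if the bracket fails to change sign).
#' @examples
#' bg_factor_approx(20, 0.95, 0.80)   # k = 2.3638
#' bg_factor_exact(20, 0.95, 0.80)    # k = 2.3654
#' @export
bg_factor_approx <- function(n, beta, gamma) {
  check_n(n)
  check_prob(beta, "beta")
  check_prob(gamma, "gamma")
  k <- normal_quantile((1 + beta) / 2) * sqrt(1 + 1 / n) *
    sqrt((n - 1) / chisq_quantile(1 - gamma, n - 1))
  new_tolerance_factor(n, beta, gamma, k, "bg_approx")
}

#' @rdname bg_factor_approx
#' @export
bg_factor_exact <- function(n, beta, gamma, rel_tol = 1e-6) {
  check_n(n)
  check_prob(beta, "beta")
  check_prob(gamma, "gamma")
  k0 <- bg_factor_approx(n, beta, gamma)$k
  f <- function(k) bg_exact_confidence(k, n, beta) - gamma
  lo <- 0.8 * k0
  hi <- 1.3 * k0
  flo <- f(lo)
  fhi <- f(hi)
  tries <- 0L
  while (flo * fhi > 0 && tries < 12L) {
    lo <- lo * 0.7
    hi <- hi * 1.4
    flo <- f(lo)
    fhi <- f(hi)
    tries <- tries + 1L
  }
  if (flo * fhi > 0)
    stop(sprintf(paste0("failed to bracket the exact tolerance factor ",
                        "(n=%d, beta=%g, gamma=%g): f(%g)=%g, f(%g)=%g"),
                 n, beta, gamma, lo, flo, hi, fhi), call. = FALSE)
  root <- stats::uniroot(f, c(lo, hi), f.lower = flo, f.upper = fhi,
                         tol = rel_tol * k0 * 1e-3)$root
  new_tolerance_factor(n, beta, gamma, root, "bg_exact")
}

#' Achieved confidence of a candidate tolerance factor
#'
#' Evaluates the left-hand side of the exact two-sided condition (see
#' [bg_factor_exact()]) at a given k: the probability that `D-bar +/- k S`
#' contains at least a proportion `beta` of the difference population.
#' Exposed so the residual of the returned root can be checked directly.
#'
#' @inheritParams bg_factor_approx
#' @param k candidate tolerance factor, > 0.
#' @return The achieved confidence in (0, 1).
#' @export
bg_exact_confidence <- function(k, n, beta) {
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k <= 0)
    stop("`k` must be a single positive number", call. = FALSE)
  check_n(n)
  check_prob(beta, "beta")
  z_max <- 10 / sqrt(n) + 8
  integrand <- function(z)
    stats::pchisq((n - 1) * stats::qchisq(beta, df = 1, ncp = z^2) / k^2,
                  df = n - 1, lower.tail = FALSE) * exp(-n * z^2 / 2)
  val <- stats::integrate(integrand, 0, z_max,
                          rel.tol = 1e-10, subdivisions = 400L)$value
  sqrt(2 * n / pi) * val
}

new_tolerance_factor <- function(n, beta, gamma, k, method) {
  structure(list(n = as.integer(n), beta = beta, gamma = gamma, k = k,
                 method = method),
            class = "tolerance_factor")
}

check_n <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 2 ||
      n != round(n))
    stop("`n` must be a single integer >= 2", call. = FALSE)
  n
}

#' @export
print.tolerance_factor <- function(x, ...) {
  cat(sprintf("Tolerance factor (%s): k = %.6f  [n = %d, beta = %g, gamma = %g]\n",
              x$method, x$k, x$n, x$beta, x$gamma))
  invisible(x)
}
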