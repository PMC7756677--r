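#' @keywords internal
new_stat_interval <- function(kind, beta, gamma, lower, upper, center, n,
                              extra = list()) {
  structure(
    c(list(kind = kind, beta = beta, gamma = gamma,
           lower = lower, upper = upper, center = center, n = n), extra),
    class = "stat_interval"
  )
}

warn_degenerate <- function(summary) {
  if (summary$sd_diff == 0)
    warning("sd_diff is zero: interval degenerates to the single point D-bar",
            call. = FALSE)
}

#' Agreement interval (Bland-Altman limits of agreement)
#'
#' Computes the classic agreement interval `D-bar +/- z * S` with
#' `z = normal_quantile((1 + beta) / 2)`.  The interval is approximate and
#' too narrow at small n because it ignores the sampling error of `D-bar`
#' and `S`; it is provided for comparison with the tolerance intervals,
#' which should be preferred.
#'
#' @param summary a [diff_summary()].
#' @param beta content level in (0, 1); default 0.95.
#' @return A `"stat_interval"` with elements `lower`, `upper`, `center`,
#'   `kind`, `beta`.
#' @examples
#' agreement_interval(diff_summary(20, -0.012, 0.047))
#' @seealso [prediction_interval()], [bg_tolerance_interval()]
#' @export
agreement_interval <- function(summary, beta = 0.95) {
  check_summary(summary)
  check_prob(beta, "beta")
  warn_degenerate(summary)
  half <- normal_quantile((1 + beta) / 2) * summary$sd_diff
  new_stat_interval("AI", beta, NA_real_,
                    summary$mean_diff - half, summary$mean_diff + half,
                    summary$mean_diff, summary$n)
}

#' Agreement interval with confidence intervals around each bound
#'
#' The agreement interval of [agreement_interval()] together with the
#' t-based confidence interval around each of its two bounds,
#' `(D-bar +/- z S) +/- t_{(1+conf)/2, n-1} * S * sqrt(1/n + z^2 / (2(n-1)))`,
#' six values in total.  The interval from the lowest to the highest of the
#' six is sometimes read as a "worst case", although it has no quantitative
#' interpretation; tolerance intervals avoid the whole construction.
#'
#' @inheritParams agreement_interval
#' @param conf confidence level of the CIs around each bound; default 0.95.
#' @return A `"stat_interval"` of kind `"AI_with_CIs"` carrying `ci_lower`
#'   and `ci_upper`, each a length-2 numeric vector (the CI of the lower and
#'   upper agreement bound respectively).
#' @examples
#' agreement_interval_cis(diff_summary(20, -0.012, 0.047))
#' @export
agreement_interval_cis <- function(summary, beta = 0.95, conf = 0.95) {
  check_summary(summary)
  check_prob(beta, "beta")
  check_prob(conf, "conf")
  warn_degenerate(summary)
  n <- summary$n
  z <- normal_quantile((1 + beta) / 2)
  half <- z * summary$sd_diff
  ci_half <- t_quantile((1 + conf) / 2, n - 1) * summary$sd_diff *
    sqrt(1 / n + z^2 / (2 * (n - 1)))
  lo <- summary$mean_diff - half
  hi <- summary$mean_diff + half
  new_stat_interval("AI_with_CIs", beta, conf, lo, hi, summary$mean_diff, n,
                    extra = list(ci_lower = c(lo - ci_half, lo + ci_half),
                                 ci_upper = c(hi - ci_half, hi + ci_half)))
}

#' Prediction interval / beta-expectation tolerance interval
#'
#' The exact two-sided interval `D-bar +/- t_{(1+beta)/2, n-1} * S *
#' sqrt(1 + 1/n)`.  Read as a prediction interval it contains one future
#' difference with confidence `beta`; read as a beta-expectation tolerance
#' interval it contains, on average over repeated studies, exactly a
#' proportion `beta` of the population of differences.  The two readings
#' share the same formula.
#'
#' @inheritParams agreement_interval
#' @return A `"stat_interval"` of kind `"PI_bTI"`.
#' @examples
#' prediction_interval(diff_summary(20, -0.012, 0.047))
#' @export
prediction_interval <- function(summary, beta = 0.95) {
  check_summary(summary)
  check_prob(beta, "beta")
  warn_degenerate(summary)
  n <- summary$n
  half <- t_quantile((1 + beta) / 2, n - 1) * summary$sd_diff * sqrt(1 + 1 / n)
  new_stat_interval("PI_bTI", beta, NA_real_,
                    summary$mean_diff - half, summary$mean_diff + half,
                    summary$mean_diff, n)
}

#' Beta-gamma content tolerance interval
#'
#' The two-sided interval `D-bar +/- k S` guaranteed to contain at least a
#' proportion `beta` of the population of differences with confidence
#' `gamma`.  `method = "approx"` uses the explicit first-order factor of
#' [bg_factor_approx()]; `method = "exact"` solves the noncentral
#' chi-square integral equation of [bg_factor_exact()].
#'
#' @inheritParams agreement_interval
#' @param gamma confidence level in (0, 1).
#' @param method `"approx"` (default) or `"exact"`.
#' @return A `"stat_interval"` of kind `"bgTI_approx"` or `"bgTI_exact"`
#'   carrying the tolerance factor as element `k`.
#' @examples
#' s <- diff_summary(20, -0.012, 0.047)
#' bg_tolerance_interval(s, gamma = 0.80)
#' bg_tolerance_interval(s, gamma = 0.80, method = "exact")
#' @export
bg_tolerance_interval <- function(summary, beta = 0.95, gamma,
                                  method = c("approx", "exact")) {
  check_summary(summary)
  method <- match.arg(method)
  fac <- if (method == "approx") bg_factor_approx(summary$n, beta, gamma)
         else bg_factor_exact(summary$n, beta, gamma)
  warn_degenerate(summary)
  half <- fac$k * summary$sd_diff
  new_stat_interval(paste0("bgTI_", method), beta, gamma,
                    summary$mean_diff - half, summary$mean_diff + half,
                    summary$mean_diff, summary$n,
                    extra = list(k = fac$k))
}

#' Sidak adjustment of a simultaneous confidence level
#'
#' When m tolerance intervals must hold simultaneously with overall
#' confidence `gamma`, each is computed at the per-comparison level
#' `gamma^(1/m)` (e.g. `0.90^(1/3) = 0.9655`).
#'
#' @param gamma overall confidence level in (0, 1).
#' @param m number of simultaneous intervals, integer >= 1.
#' @return The per-comparison confidence level.
#' @examples
#' sidak_adjust(0.90, 3)
#' @export
sidak_adjust <- function(gamma, m) {
  check_prob(gamma, "gamma")
  if (!is.numeric(m) || length(m) != 1L || !is.finite(m) || m < 1 ||
      m != round(m))
    stop("`m` must be a single integer >= 1", call. = FALSE)
  gamma^(1 / m)
}

#' Interval width
#' @param x a `"stat_interval"`.
#' @return `upper - lower`.
#' @export
interval_width <- function(x) {
  stopifnot(inherits(x, "stat_interval"))
  x$upper - x$lower
}

#' @export
print.stat_interval <- function(x, digits = 3, ...) {
  lab <- switch(x$kind,
    AI          = sprintf("%g%% agreement interval", 100 * x$beta),
    AI_with_CIs = sprintf("%g%% agreement interval with %g%% CIs",
                          100 * x$beta, 100 * x$gamma),
    PI_bTI      = sprintf("%g%% prediction interval (beta-expectation TI)",
                          100 * x$beta),
    bgTI_approx = sprintf("%g%% tolerance interval, %g%% confidence (approx k)",
                          100 * x$beta, 100 * x$gamma),
    bgTI_exact  = sprintf("%g%% tolerance interval, %g%% confidence (exact k)",
                          100 * x$beta, 100 * x$gamma),
    bootstrap_t_PI = sprintf("%g%% bootstrap-t prediction interval",
                             100 * x$beta),
    x$kind)
  cat(sprintf("%s: [%s, %s]\n", lab,
              format(round(x$lower, digits)), format(round(x$upper, digits))))
  if (x$kind == "AI_with_CIs") {
    cat(sprintf("  lower bound CI: [%s, %s]\n",
                format(round(x$ci_lower[1], digits)),
                format(round(x$ci_lower[2], digits))))
    cat(sprintf("  upper bound CI: [%s, %s]\n",
                format(round(x$ci_upper[1], digits)),
                format(round(x$ci_upper[2], digits))))
  }
  invisible(x)
}
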