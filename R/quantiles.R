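#' Quantiles used by the interval formulas
#'
#' Validated wrappers around the standard-normal, Student-t and central
#' chi-square quantile functions.  All probabilities are cumulative from the
#' left, so the upper two-sided bound at content level `beta` uses
#' `normal_quantile((1 + beta) / 2)`.
#'
#' @param p probability in (0, 1).
#' @param df degrees of freedom, at least 1.
#' @return The requested quantile as a numeric scalar.
#' @examples
#' normal_quantile(0.975)      # 1.96
#' t_quantile(0.975, 19)       # 2.093
#' chisq_quantile(0.20, 19)    # 13.716
#' @name quantiles
NULL

check_prob <- function(p, what = "p") {
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p <= 0 || p >= 1)
    stop("`", what, "` must be a single probability strictly inside (0, 1)",
         call. = FALSE)
  p
}

check_df <- function(df) {
  if (!is.numeric(df) || length(df) != 1L || !is.finite(df) || df < 1)
    stop("`df` must be a single number >= 1", call. = FALSE)
  df
}

#' @rdname quantiles
#' @export
normal_quantile <- function(p) {
  stats::qnorm(check_prob(p))
}

#' @rdname quantiles
#' @export
t_quantile <- function(p, df) {
  stats::qt(check_prob(p), df = check_df(df))
}

#' @rdname quantiles
#' @export
chisq_quantile <- function(p, df) {
  stats::qchisq(check_prob(p), df = check_df(df))
}
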