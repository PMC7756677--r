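#' Full mean-difference analysis of a paired sample
#'
#' The main pipeline: builds the (M, D) data (averaging replicates per
#' subject per method, optionally on a log scale), summarizes the
#' differences, computes the agreement interval (with CIs around its
#' bounds), the prediction / beta-expectation tolerance interval and — when
#' a confidence level `gamma` is supplied — the beta-gamma content
#' tolerance interval with both the approximate and the exact factor, runs
#' the Shapiro-Wilk normality check on the differences, and applies the
#' equivalence decision rule against an optional acceptance interval.
#'
#' Equivalence is concluded only when every requested tolerance interval
#' (the beta-expectation TI and, if computed, the beta-gamma content TI)
#' lies entirely inside the acceptance band; for a percentage or
#' two-threshold band the check is pointwise over the observed range of
#' mean measures.  The agreement interval never enters the decision.
#'
#' @param sample a [paired_sample()].
#' @param beta content / predictive level, default 0.95.
#' @param gamma optional confidence level for the beta-gamma content TI;
#'   when `NULL` (default) no content TI is computed — the confidence level
#'   is to be chosen a priori from the study objectives.
#' @param transform `"none"`, `"log10"` or `"ln"`.
#' @param acceptance optional [acceptance_spec()].
#' @param conf confidence level of the CIs around the agreement-interval
#'   bounds; default 0.95.
#' @return An `"md_result"`: list with `summary` ([diff_summary()]),
#'   `intervals` (named list of `"stat_interval"`), `normality_p`, `md`
#'   (the [build_md()] data), `acceptance`, `decision` (one of
#'   `"equivalent"`, `"not_demonstrated"`, `"not_assessed"`), `scale`,
#'   `back_transformed`, `base`.
#' @examples
#' s <- generate_paired_fixture(20, -0.012, 0.047, seed = 3)
#' s <- calibrate_to_summary(s, -0.012, 0.047)
#' md_analyze(s, gamma = 0.80, acceptance = acceptance_spec(0.1))
#' @export
md_analyze <- function(sample, beta = 0.95, gamma = NULL,
                       transform = c("none", "log10", "ln"),
                       acceptance = NULL, conf = 0.95) {
  transform <- match.arg(transform)
  md <- build_md(sample, transform)
  if (length(md$diffs) < 3L)
    stop("at least 3 subjects are required", call. = FALSE)
  if (!is.null(acceptance) && !inherits(acceptance, "acceptance_spec"))
    stop("`acceptance` must be an `acceptance_spec`", call. = FALSE)
  if (!is.null(acceptance) && !is.null(acceptance$ratio_fraction) &&
      transform == "none")
    stop("a ratio acceptance band requires a log transform", call. = FALSE)

  summ <- summarize_diffs(md$diffs)
  intervals <- list(
    AI = agreement_interval(summ, beta),
    AI_with_CIs = agreement_interval_cis(summ, beta, conf),
    PI_bTI = prediction_interval(summ, beta)
  )
  if (!is.null(gamma)) {
    intervals$bgTI_approx <- bg_tolerance_interval(summ, beta, gamma, "approx")
    intervals$bgTI_exact <- bg_tolerance_interval(summ, beta, gamma, "exact")
  }

  res <- structure(
    list(summary = summ, intervals = intervals,
         normality_p = normality_check(md$diffs),
         md = md, acceptance = acceptance, decision = "not_assessed",
         scale = transform, back_transformed = FALSE, base = NA_real_,
         beta = beta, gamma = gamma),
    class = "md_result")
  res$decision <- evaluate_decision(res)
  res
}

# intersection of the acceptance band over the observed means, on the
# current analysis scale; NULL when no decision can be made
decision_band <- function(res) {
  acc <- res$acceptance
  if (is.null(acc)) return(NULL)
  if (!is.null(acc$ratio_fraction)) {
    f <- acc$ratio_fraction
    if (res$back_transformed) return(c(1 - f, 1 / (1 - f)))
    if (res$scale == "none") return(NULL)
    lg <- if (res$scale == "log10") log10 else log
    return(c(lg(1 - f), -lg(1 - f)))
  }
  if (res$scale != "none")
    return(NULL)  # absolute bands are defined on the raw scale only
  band <- acceptance_band(acc, res$md$means)
  c(max(band[, "lower"]), min(band[, "upper"]))
}

evaluate_decision <- function(res) {
  band <- decision_band(res)
  if (is.null(band)) return("not_assessed")
  checked <- res$intervals[intersect(
    c("PI_bTI", "bgTI_exact", "bgTI_approx"), names(res$intervals))]
  if (!length(checked)) return("not_assessed")
  inside <- vapply(checked, function(iv)
    iv$lower >= band[1] && iv$upper <= band[2], logical(1))
  if (all(inside)) "equivalent" else "not_demonstrated"
}

#' Shapiro-Wilk normality check on the differences
#'
#' Advisory only: the p-value is reported alongside the intervals and never
#' blocks their computation.  Defined for 3 to 5000 observations with
#' non-zero spread; otherwise `NA` with a warning.
#'
#' @param diffs numeric vector of differences.
#' @return The Shapiro-Wilk p-value, or `NA` when the test is undefined.
#' @export
normality_check <- function(diffs) {
  if (!is.numeric(diffs))
    stop("`diffs` must be numeric", call. = FALSE)
  n <- length(diffs)
  if (n < 3 || n > 5000) {
    warning("Shapiro-Wilk test requires 3 to 5000 observations; ",
            "p-value not computed", call. = FALSE)
    return(NA_real_)
  }
  if (stats::sd(diffs) == 0) {
    warning("differences are constant; normality test undefined",
            call. = FALSE)
    return(NA_real_)
  }
  stats::shapiro.test(diffs)$p.value
}

#' Back-transform a log-scale analysis to the ratio scale
#'
#' Maps every interval bound b of a log-scale [md_analyze()] result to
#' `base^b`, so differences become ratios and per-subject means become
#' geometric means; the centre becomes the geometric-mean ratio of the two
#' methods.  If the acceptance specification carries a `ratio_fraction` f,
#' the acceptance bounds `(1 - f, 1/(1 - f))` are applied and the
#' equivalence decision re-evaluated on the ratio scale.
#'
#' @param result an `"md_result"` computed with a log transform.
#' @param base `10` or `exp(1)`; defaults to the base of the transform
#'   used in the analysis.
#' @return The back-transformed `"md_result"` (`back_transformed = TRUE`).
#' @examples
#' s <- generate_paired_fixture(11, 0.2, 0.4, base_level = 0.05,
#'                              base_sd = 0.3, seed = 9)
#' s$x <- abs(s$x); s$y <- abs(s$y)
#' r <- md_analyze(s, gamma = 0.8, transform = "log10")
#' antilog_intervals(r)
#' @export
antilog_intervals <- function(result, base = NULL) {
  if (!inherits(result, "md_result"))
    stop("`result` must be an `md_result`", call. = FALSE)
  if (result$scale == "none")
    stop("result was computed on the raw scale; nothing to back-transform",
         call. = FALSE)
  if (result$back_transformed)
    stop("result is already back-transformed", call. = FALSE)
  if (is.null(base)) base <- if (result$scale == "log10") 10 else exp(1)
  if (!base %in% c(10, exp(1)))
    stop("`base` must be 10 or exp(1)", call. = FALSE)

  pow <- function(b) base^b
  result$intervals <- lapply(result$intervals, function(iv) {
    iv$lower <- pow(iv$lower)
    iv$upper <- pow(iv$upper)
    iv$center <- pow(iv$center)
    if (!is.null(iv$ci_lower)) iv$ci_lower <- pow(iv$ci_lower)
    if (!is.null(iv$ci_upper)) iv$ci_upper <- pow(iv$ci_upper)
    iv
  })
  result$md$means <- pow(result$md$means)
  result$md$diffs <- pow(result$md$diffs)
  result$back_transformed <- TRUE
  result$base <- base
  result$decision <- evaluate_decision(result)
  result
}

#' @export
print.md_result <- function(x, digits = 3, ...) {
  s <- x$summary
  unitlab <- if (x$back_transformed) " (ratio scale)"
             else if (x$scale != "none") paste0(" (", x$scale, " scale)")
             else ""
  cat(sprintf("Mean-difference analysis%s: %s vs %s\n", unitlab,
              x$md$method_names[1], x$md$method_names[2]))
  cat(sprintf("  n = %d, mean diff = %s, sd = %s\n", s$n,
              format(round(s$mean_diff, digits + 1)),
              format(round(s$sd_diff, digits + 1))))
  if (!is.na(x$normality_p))
    cat(sprintf("  Shapiro-Wilk p = %s (on the analysis scale)\n",
                format(round(x$normality_p, 2))))
  for (iv in x$intervals) print(iv, digits = digits)
  cat("  Equivalence decision: ", x$decision, "\n", sep = "")
  invisible(x)
}
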