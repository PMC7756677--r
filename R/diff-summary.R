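#' Sufficient statistics of the paired differences
#'
#' Every interval in the package is a function of three numbers only: the
#' number of subjects `n`, the mean of the paired differences `mean_diff`
#' (D-bar) and their sample standard deviation `sd_diff` (S, divisor n - 1).
#' `diff_summary()` builds the object from the statistics themselves (for
#' example the printed summary of a published study); `summarize_diffs()`
#' computes them from a vector of differences.
#'
#' @param n integer subject count, at least 2.
#' @param mean_diff mean difference, in measurement units.
#' @param sd_diff standard deviation of the differences (divisor n - 1),
#'   same units; must be non-negative.
#' @return An object of class `"diff_summary"`: a list with elements `n`,
#'   `mean_diff`, `sd_diff`.
#' @examples
#' # the 20-dog erythrocyte comparison, from its printed summary statistics
#' s <- diff_summary(20, -0.012, 0.047)
#' agreement_interval(s)
#' @export
diff_summary <- function(n, mean_diff, sd_diff) {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 2 ||
      n != round(n))
    stop("`n` must be a single integer >= 2", call. = FALSE)
  if (!is.numeric(mean_diff) || length(mean_diff) != 1L || !is.finite(mean_diff))
    stop("`mean_diff` must be a single finite number", call. = FALSE)
  if (!is.numeric(sd_diff) || length(sd_diff) != 1L || !is.finite(sd_diff) ||
      sd_diff < 0)
    stop("`sd_diff` must be a single non-negative number", call. = FALSE)
  structure(
    list(n = as.integer(n), mean_diff = mean_diff, sd_diff = sd_diff),
    class = "diff_summary"
  )
}

#' @param diffs numeric vector of paired differences (length >= 2, finite).
#' @rdname diff_summary
#' @export
summarize_diffs <- function(diffs) {
  if (!is.numeric(diffs) || length(diffs) < 2L || anyNA(diffs) ||
      !all(is.finite(diffs)))
    stop("`diffs` must be a finite numeric vector of length >= 2",
         call. = FALSE)
  diff_summary(length(diffs), mean(diffs), stats::sd(diffs))
}

#' @export
print.diff_summary <- function(x, ...) {
  cat(sprintf("Difference summary: n = %d, mean = %g, sd = %g\n",
              x$n, x$mean_diff, x$sd_diff))
  invisible(x)
}

check_summary <- function(summary) {
  if (!inherits(summary, "diff_summary"))
    stop("`summary` must be a `diff_summary` object", call. = FALSE)
  summary
}
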