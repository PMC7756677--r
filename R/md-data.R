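#' Build mean-difference data from a paired sample
#'
#' Averages replicates per subject per method, optionally log-transforms,
#' and derives the quantities of the mean-difference (Bland-Altman) plot:
#' per-subject means `M = (x_mean + y_mean) / 2` and differences
#' `D = x_mean - y_mean`, both on the analysis scale.  On a log scale the
#' antilog of M is the geometric mean and the antilog of D the ratio of
#' the two methods.
#'
#' @param sample a [paired_sample()].
#' @param transform `"none"` (default), `"log10"` or `"ln"`.
#' @return An `"md_data"`: list with `means`, `diffs`, `scale`,
#'   `method_names`, `subject_ids`.
#' @examples
#' s <- paired_sample(c(10, 100), c(1, 10))
#' build_md(s, transform = "log10")
#' @export
build_md <- function(sample, transform = c("none", "log10", "ln")) {
  if (!inherits(sample, "paired_sample"))
    stop("`sample` must be a `paired_sample`", call. = FALSE)
  transform <- match.arg(transform)
  xm <- sample$x
  ym <- sample$y
  if (transform != "none") {
    bad <- which(rowSums(xm <= 0) + rowSums(ym <= 0) > 0)
    if (length(bad))
      stop("log transform requires positive measurements; subject(s) ",
           paste(utils::head(sample$subject_ids[bad], 5), collapse = ", "),
           " have non-positive values", call. = FALSE)
    f <- if (transform == "log10") log10 else log
    xm <- f(xm)
    ym <- f(ym)
  }
  x_mean <- rowMeans(xm)
  y_mean <- rowMeans(ym)
  structure(list(means = (x_mean + y_mean) / 2,
                 diffs = x_mean - y_mean,
                 scale = transform,
                 method_names = sample$method_names,
                 subject_ids = sample$subject_ids),
            class = "md_data")
}

#' @export
print.md_data <- function(x, ...) {
  cat(sprintf("MD data: %d subjects, scale = %s\n", length(x$diffs), x$scale))
  invisible(x)
}

#' Clinical acceptance interval specification
#'
#' Describes the band of tolerable differences.  Four forms: a constant
#' band `+/- delta`; a two-threshold band using `delta` below `threshold`
#' (strictly) and `delta2` at or above it; a percentage band
#' `+/- (delta/100) * M` growing with the mean measure; and a ratio band
#' `(1 - f, 1/(1 - f))` for log-scale analyses after back-transformation.
#'
#' @param delta tolerated absolute difference (or percentage when
#'   `percent = TRUE`), > 0.
#' @param delta2 optional second tolerance used at or above `threshold`.
#' @param threshold optional cutoff on the mean measure M switching from
#'   `delta` to `delta2`.
#' @param percent if `TRUE`, `delta` is a percentage of M.
#' @param ratio_fraction optional tolerated relative difference f in (0, 1)
#'   on the ratio scale; acceptance bounds become `1 - f` and `1/(1 - f)`.
#' @return An `"acceptance_spec"`.
#' @examples
#' acceptance_spec(0.1)                    # constant +/- 0.1
#' acceptance_spec(10, percent = TRUE)     # +/- 10% of the mean
#' acceptance_spec(1, delta2 = 2, threshold = 15)
#' acceptance_spec(0.2, ratio_fraction = 0.2)
#' @export
acceptance_spec <- function(delta, delta2 = NULL, threshold = NULL,
                            percent = FALSE, ratio_fraction = NULL) {
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0)
    stop("`delta` must be a single positive number", call. = FALSE)
  if (!is.null(threshold) && is.null(delta2))
    stop("`delta2` must be given when `threshold` is set", call. = FALSE)
  if (!is.null(delta2) && is.null(threshold))
    stop("`threshold` must be given when `delta2` is set", call. = FALSE)
  if (!is.null(delta2) && (!is.numeric(delta2) || delta2 <= 0))
    stop("`delta2` must be positive", call. = FALSE)
  if (!is.null(ratio_fraction) &&
      (!is.numeric(ratio_fraction) || ratio_fraction <= 0 ||
       ratio_fraction >= 1))
    stop("`ratio_fraction` must lie in (0, 1)", call. = FALSE)
  if (isTRUE(percent) && !is.null(delta2))
    stop("percentage and two-threshold forms cannot be combined",
         call. = FALSE)
  structure(list(delta1 = delta, delta2 = delta2, threshold = threshold,
                 percent = isTRUE(percent), ratio_fraction = ratio_fraction),
            class = "acceptance_spec")
}

#' Evaluate the acceptance band at a mean value
#'
#' Returns the (lower, upper) tolerated difference at mean measure `m`:
#' constant `+/- delta`; percentage `+/- (delta/100) * m` (the higher the
#' measure, the wider the band); two-threshold `+/- delta1` strictly below
#' the threshold and `+/- delta2` at or above it.
#'
#' @param spec an [acceptance_spec()].
#' @param m mean measure(s) on the x-axis; vectorized.
#' @return A matrix with columns `lower`, `upper`, one row per `m`.
#' @examples
#' acceptance_band(acceptance_spec(10, percent = TRUE), c(10, 20))
#' @export
acceptance_band <- function(spec, m) {
  if (!inherits(spec, "acceptance_spec"))
    stop("`spec` must be an `acceptance_spec`", call. = FALSE)
  if (spec$percent && any(m < 0))
    stop("percentage band is undefined for negative mean measures",
         call. = FALSE)
  upper <- if (spec$percent) {
    (spec$delta1 / 100) * m
  } else if (!is.null(spec$threshold)) {
    ifelse(m < spec$threshold, spec$delta1, spec$delta2)
  } else {
    rep(spec$delta1, length(m))
  }
  cbind(lower = -upper, upper = upper)
}
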