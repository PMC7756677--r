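#' Simulate paired differences under equivalence
#'
#' Draws the differences of an unreplicated method-comparison design in
#' which both devices measure the same true value and each adds an
#' independent Gaussian error: `D = e_x - e_y ~ Normal(0, sqrt(sd_x^2 +
#' sd_y^2))`.  Uses the current RNG stream.
#'
#' @param n number of subjects, >= 2.
#' @param sd_x,sd_y error standard deviations of the two devices;
#'   default 1 each, giving true difference SD `sqrt(2) = 1.414`.
#' @return Numeric vector of n differences.
#' @export
simulate_differences <- function(n, sd_x = 1, sd_y = 1) {
  check_n(n)
  if (sd_x < 0 || sd_y < 0) stop("error SDs must be >= 0", call. = FALSE)
  stats::rnorm(n, 0, sqrt(sd_x^2 + sd_y^2))
}

#' Effective content of an interval under the true difference law
#'
#' The probability mass of `Normal(true_mean, true_sd)` captured by the
#' interval, computed analytically:
#' `pnorm((upper - mu)/sigma) - pnorm((lower - mu)/sigma)`.  No inner
#' simulation is involved.
#'
#' @param interval a `"stat_interval"`, or a numeric `c(lower, upper)`.
#' @param true_mean,true_sd parameters of the true difference
#'   distribution; `true_sd > 0`.
#' @return The content probability in `[0, 1]`.
#' @examples
#' effective_level(c(-1.96, 1.96) * sqrt(2), 0, sqrt(2))  # 0.95
#' @export
effective_level <- function(interval, true_mean = 0, true_sd) {
  if (inherits(interval, "stat_interval"))
    interval <- c(interval$lower, interval$upper)
  if (!is.numeric(interval) || length(interval) != 2L)
    stop("`interval` must be a stat_interval or c(lower, upper)",
         call. = FALSE)
  if (!is.numeric(true_sd) || true_sd <= 0)
    stop("`true_sd` must be > 0", call. = FALSE)
  stats::pnorm((interval[2] - true_mean) / true_sd) -
    stats::pnorm((interval[1] - true_mean) / true_sd)
}

#' Monte-Carlo study of effective predictive and confidence levels
#'
#' For each sample size in `n_grid`, simulates `reps` unreplicated studies
#' under equivalence, computes the agreement interval, the
#' beta-expectation tolerance interval and the beta-gamma content
#' tolerance intervals (approximate and/or exact factor, one per `gammas`
#' entry), and evaluates each interval's analytic content under the true
#' difference distribution.  Reports per (n, interval): the mean effective
#' predictive level, its Monte-Carlo standard error, and — for the content
#' TIs — the effective confidence level, i.e. the fraction of studies
#' whose content is at least `beta`, with its binomial MC standard error.
#'
#' The master seed deterministically spawns one substream per sample size,
#' so the grid is reproducible and each n's results do not depend on the
#' other grid entries.
#'
#' @param n_grid integer vector of sample sizes (each >= 2).
#' @param reps number of simulated studies per n; default 10000.
#' @param beta predictive / content level; default 0.95.
#' @param gammas confidence levels for the content TIs; default
#'   `c(0.80, 0.90, 0.95)`.
#' @param sd_x,sd_y device error SDs; default 1.
#' @param seed master seed; default 1.
#' @param methods which content-TI factor(s) to evaluate: subset of
#'   `c("approx", "exact")`.
#' @return A `"coverage_grid"` data frame with one row per (n, interval):
#'   columns `n`, `interval`, `beta`, `gamma`, `mean_effective_level`,
#'   `mc_se_level`, `effective_confidence`, `mc_se_confidence`, `reps`.
#' @examples
#' run_coverage_study(c(5, 20), reps = 2000, gammas = 0.8, seed = 42)
#' @export
run_coverage_study <- function(n_grid, reps = 10000L, beta = 0.95,
                               gammas = c(0.80, 0.90, 0.95),
                               sd_x = 1, sd_y = 1, seed = 1L,
                               methods = c("approx", "exact")) {
  if (!is.numeric(n_grid) || !length(n_grid) || any(n_grid < 2))
    stop("`n_grid` must contain sample sizes >= 2", call. = FALSE)
  if (reps < 1) stop("`reps` must be >= 1", call. = FALSE)
  check_prob(beta, "beta")
  for (g in gammas) check_prob(g, "gamma")
  methods <- match.arg(methods, several.ok = TRUE)
  n_grid <- as.integer(n_grid)
  true_sd <- sqrt(sd_x^2 + sd_y^2)

  old <- local_rng_seed(seed)
  on.exit(restore_rng_seed(old), add = TRUE)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, length(n_grid))

  rows <- list()
  for (i in seq_along(n_grid)) {
    n <- n_grid[i]
    set.seed(sub_seeds[i])
    d <- matrix(stats::rnorm(n * reps, 0, true_sd), nrow = n)
    m <- colMeans(d)
    s <- matrixColSds(d, m)

    content_of <- function(k) {
      stats::pnorm((m + k * s) / true_sd) - stats::pnorm((m - k * s) / true_sd)
    }
    record <- function(interval, gamma, k) {
      cont <- content_of(k)
      conf <- mean(cont >= beta)
      rows[[length(rows) + 1L]] <<- data.frame(
        n = n, interval = interval, beta = beta, gamma = gamma,
        mean_effective_level = mean(cont),
        mc_se_level = stats::sd(cont) / sqrt(reps),
        effective_confidence = conf,
        mc_se_confidence = sqrt(conf * (1 - conf) / reps),
        reps = as.integer(reps))
    }

    record("AI", NA_real_, normal_quantile((1 + beta) / 2))
    record("bTI", NA_real_, t_quantile((1 + beta) / 2, n - 1) * sqrt(1 + 1 / n))
    for (g in gammas) {
      if ("approx" %in% methods)
        record("bgTI_approx", g, bg_factor_approx(n, beta, g)$k)
      if ("exact" %in% methods)
        record("bgTI_exact", g, bg_factor_exact(n, beta, g)$k)
    }
  }
  structure(do.call(rbind, rows),
            class = c("coverage_grid", "data.frame"),
            seed = as.integer(seed), sd_x = sd_x, sd_y = sd_y)
}

#' @export
print.coverage_grid <- function(x, ...) {
  cat("Coverage study (seed ", attr(x, "seed"), ", true diff SD ",
      format(sqrt(attr(x, "sd_x")^2 + attr(x, "sd_y")^2)), "):\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write a coverage grid to CSV
#' @param grid a `"coverage_grid"`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_coverage_csv <- function(grid, path) {
  stopifnot(inherits(grid, "coverage_grid"))
  utils::write.csv(as.data.frame(grid), path, row.names = FALSE)
  invisible(path)
}
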