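#' Bootstrap-t prediction interval for paired differences
#'
#' Nonparametric analogue of [prediction_interval()].  The t-based interval
#' rests on the pivot `(D_future - D-bar) / (S sqrt(1 + 1/n))`; here the
#' differences are resampled with replacement and at each resample the
#' bootstrap version of that root, `r = (d* - D-bar*) / (S* sqrt(1 + 1/n))`
#' with `d*` one further draw from the data, is computed.  The Student
#' quantiles are then replaced by the empirical `(1 - beta)/2` and
#' `(1 + beta)/2` quantiles of the root distribution.  Coverage is known
#' to fall slightly below the nominal level at small n.
#'
#' @param diffs numeric vector of differences, length >= 3.
#' @param beta content level in (0, 1); default 0.95.
#' @param n_boot number of bootstrap resamples, >= 100; default 2000.
#' @param seed integer seed making the interval reproducible; default 1.
#' @return A `"stat_interval"` of kind `"bootstrap_t_PI"`; element
#'   `n_degenerate` counts resamples skipped for zero resample SD.
#' @examples
#' set.seed(42)
#' bootstrap_t_pi(rnorm(30), seed = 7)
#' @export
bootstrap_t_pi <- function(diffs, beta = 0.95, n_boot = 2000L, seed = 1L) {
  if (!is.numeric(diffs) || length(diffs) < 3L || anyNA(diffs) ||
      !all(is.finite(diffs)))
    stop("`diffs` must be a finite numeric vector of length >= 3",
         call. = FALSE)
  check_prob(beta, "beta")
  if (!is.numeric(n_boot) || length(n_boot) != 1L || n_boot < 100)
    stop("`n_boot` must be at least 100", call. = FALSE)
  n <- length(diffs)
  dbar <- mean(diffs)
  s <- stats::sd(diffs)
  if (s == 0)
    stop("differences have zero spread: bootstrap pivot is undefined",
         call. = FALSE)
  fac <- sqrt(1 + 1 / n)

  old <- local_rng_seed(seed)
  on.exit(restore_rng_seed(old), add = TRUE)

  boot <- matrix(diffs[sample.int(n, n * n_boot, replace = TRUE)], nrow = n)
  m_star <- colMeans(boot)
  s_star <- matrixColSds(boot, m_star)
  future <- diffs[sample.int(n, n_boot, replace = TRUE)]
  keep <- s_star > 0
  n_degenerate <- sum(!keep)
  r <- (future[keep] - m_star[keep]) / (s_star[keep] * fac)
  q <- stats::quantile(r, probs = c((1 - beta) / 2, (1 + beta) / 2),
                       names = FALSE, type = 7)
  new_stat_interval("bootstrap_t_PI", beta, NA_real_,
                    dbar + q[1] * s * fac, dbar + q[2] * s * fac, dbar, n,
                    extra = list(n_boot = as.integer(n_boot),
                                 n_degenerate = as.integer(n_degenerate)))
}

# column SDs (divisor n-1) given precomputed column means
matrixColSds <- function(x, means) {
  sqrt(colSums(sweep(x, 2, means)^2) / (nrow(x) - 1))
}

# save the RNG state, seed deterministically, and allow restoration so that
# seeded helpers do not disturb the caller's stream
local_rng_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  old
}

restore_rng_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
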