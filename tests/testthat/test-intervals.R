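# Frozen expected values: direct evaluation of the closed-form interval
# formulas with unrounded quantiles (qnorm/qt/qchisq at double precision).

test_that("agreement interval matches the erythrocyte worked example", {
  ai <- agreement_interval(dog_summary())
  expect_equal(ai$lower, -0.10411831, tolerance = 1e-7)
  expect_equal(ai$upper, 0.08011831, tolerance = 1e-7)
  expect_equal(round(ai$upper, 3), 0.080)
  expect_equal(round(ai$lower, 3), -0.104)  # paper prints -0.103 from unrounded stats
  expect_identical(ai$kind, "AI")
})

test_that("CIs around the agreement bounds match direct evaluation", {
  ai <- agreement_interval_cis(dog_summary())
  expect_equal(ai$ci_upper, c(0.04188064, 0.11835598), tolerance = 1e-7)
  expect_equal(ai$ci_lower, c(-0.14235598, -0.06588064), tolerance = 1e-7)
  expect_equal(round(ai$ci_upper[1], 3), 0.042)
  # zero spread: all six values collapse onto the mean
  expect_warning(d0 <- agreement_interval_cis(diff_summary(10, 0.3, 0)),
                 "degenerate")
  expect_equal(unique(c(d0$lower, d0$upper, d0$ci_lower, d0$ci_upper)), 0.3)
})

test_that("prediction interval matches direct evaluation of the t formula", {
  pi_ <- prediction_interval(dog_summary())
  expect_equal(pi_$lower, -0.11280144, tolerance = 1e-7)
  expect_equal(pi_$upper, 0.08880144, tolerance = 1e-7)
  # minimal sample size: t(0.975, 1) * sqrt(3/2)
  p2 <- prediction_interval(diff_summary(2, 0, 1))
  expect_equal(p2$upper, 15.561859, tolerance = 1e-5)
  # converges to the agreement interval as n grows
  big <- diff_summary(10^7, -0.012, 0.047)
  expect_equal(prediction_interval(big)$upper, agreement_interval(big)$upper,
               tolerance = 1e-6)
})

test_that("approximate content-TI factor and interval match direct evaluation", {
  fac <- bg_factor_approx(20, 0.95, 0.80)
  expect_equal(fac$k, 2.3637913, tolerance = 1e-6)
  ti <- bg_tolerance_interval(dog_summary(), gamma = 0.80)
  expect_equal(ti$lower, -0.12309819, tolerance = 1e-7)
  expect_equal(ti$upper, 0.09909819, tolerance = 1e-7)
  # large-n limit: k -> z; the approach is slow, O(1/sqrt(n)) through the
  # chi-square quantile
  expect_equal(bg_factor_approx(10^7, 0.95, 0.80)$k, qnorm(0.975),
               tolerance = 1e-3)
  expect_lt(abs(bg_factor_approx(10^7, 0.95, 0.80)$k - qnorm(0.975)),
            abs(bg_factor_approx(10^5, 0.95, 0.80)$k - qnorm(0.975)))
  # wider when more confidence is requested
  ks <- vapply(c(0.6, 0.8, 0.9, 0.95, 0.99),
               function(g) bg_factor_approx(20, 0.95, g)$k, numeric(1))
  expect_true(all(diff(ks) > 0))
})

test_that("intervals are symmetric about the mean difference", {
  for (s in random_summaries(25)) {
    for (iv in list(agreement_interval(s), prediction_interval(s),
                    bg_tolerance_interval(s, gamma = 0.9))) {
      expect_equal(iv$center - iv$lower, iv$upper - iv$center,
                   tolerance = 1e-12)
    }
  }
})

test_that("interval nesting holds at the study confidence levels", {
  # AI inside bTI inside bgTI, checked for gamma in {0.8, 0.9, 0.95};
  # near gamma = 0.5 the content TI is only similar to, not wider than,
  # the beta-expectation TI, so nesting is asserted at the levels a study
  # would actually use
  cases <- random_summaries(200)
  gammas <- c(0.8, 0.9, 0.95)
  for (i in seq_along(cases)) {
    s <- cases[[i]]
    ai <- agreement_interval(s)
    pi_ <- prediction_interval(s)
    bg <- bg_tolerance_interval(s, gamma = gammas[(i %% 3) + 1])
    expect_gt(ai$lower, pi_$lower - 1e-12)
    expect_lt(ai$upper, pi_$upper + 1e-12)
    expect_gt(pi_$lower, bg$lower - 1e-12)
    expect_lt(pi_$upper, bg$upper + 1e-12)
  }
})

test_that("intervals are location-shift invariant and scale equivariant", {
  s <- diff_summary(17, 1.3, 0.8)
  a <- 3.7; b <- -2.1
  shifted <- diff_summary(17, 1.3 + b, 0.8)
  scaled <- diff_summary(17, a * 1.3, a * 0.8)
  for (f in list(agreement_interval, prediction_interval,
                 function(x) bg_tolerance_interval(x, gamma = 0.9))) {
    iv <- f(s)
    expect_equal(f(shifted)$lower, iv$lower + b, tolerance = 1e-12)
    expect_equal(f(shifted)$upper, iv$upper + b, tolerance = 1e-12)
    expect_equal(f(scaled)$lower, a * iv$lower, tolerance = 1e-12)
    expect_equal(f(scaled)$upper, a * iv$upper, tolerance = 1e-12)
  }
})

test_that("width gaps between the intervals shrink with n", {
  gap_ai <- function(n) {
    s <- diff_summary(n, 0, 1)
    abs(interval_width(agreement_interval(s)) /
          interval_width(prediction_interval(s)) - 1)
  }
  gap_bg <- function(n) {
    s <- diff_summary(n, 0, 1)
    abs(interval_width(bg_tolerance_interval(s, gamma = 0.8)) /
          interval_width(prediction_interval(s)) - 1)
  }
  ns <- c(10, 100, 1000, 10^4)
  expect_true(all(diff(vapply(ns, gap_ai, numeric(1))) < 0))
  expect_true(all(diff(vapply(ns, gap_bg, numeric(1))) < 0))
  # the AI/bTI gap decays like 1/n: ~0.17% at n = 10^3, below 0.1% by 2x10^3
  expect_lt(gap_ai(1000), 2e-3)
  expect_lt(gap_ai(2000), 1e-3)
  # the bgTI/bTI gap decays like |z_{1-gamma}| sqrt(2/n)/2, an order of
  # magnitude slower: ~0.6% at n = 10^4, ~0.2% at n = 10^5
  expect_lt(gap_bg(10^4), 7e-3)
  expect_lt(gap_bg(10^5), 2.5e-3)
})

test_that("Sidak adjustment returns the per-comparison level", {
  expect_equal(sidak_adjust(0.90, 3), 0.9655, tolerance = 1e-4)
  expect_identical(sidak_adjust(0.77, 1), 0.77)
  expect_equal(sidak_adjust(0.95, 2), 0.9747, tolerance = 1e-4)
  expect_error(sidak_adjust(1.1, 2), "probability")
  expect_error(sidak_adjust(0.9, 0), "integer")
})

test_that("degenerate and invalid inputs are signalled", {
  expect_warning(ai <- agreement_interval(diff_summary(5, 0, 0)),
                 "degenerate")
  expect_equal(c(ai$lower, ai$upper), c(0, 0))
  expect_error(diff_summary(1, 0, 1), "n")
  expect_error(diff_summary(10, 0, -1), "non-negative")
  expect_error(agreement_interval(dog_summary(), beta = 1), "probability")
})
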