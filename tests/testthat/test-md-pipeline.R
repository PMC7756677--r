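test_that("build_md averages replicates and computes M and D", {
  s <- paired_sample(c(1, 2, 3), c(1, 2, 3))
  md <- build_md(s)
  expect_equal(md$diffs, c(0, 0, 0))
  expect_equal(md$means, c(1, 2, 3))

  sl <- build_md(paired_sample(c(10, 100), c(1, 10)), transform = "log10")
  expect_equal(sl$diffs, c(1, 1))
  expect_equal(sl$means, c(0.5, 1.5))

  sr <- paired_sample(rbind(c(1, 3), c(2, 4)), c(0, 0))
  expect_equal(build_md(sr)$diffs, c(2, 3))

  expect_error(build_md(paired_sample(c(1, -2, 3), c(1, 1, 1)),
                        transform = "log10"), "positive")
})

test_that("analysis of the calibrated erythrocyte fixture reproduces the intervals", {
  r <- md_analyze(dog_sample(), gamma = 0.80,
                  acceptance = acceptance_spec(0.1))
  expect_equal(r$summary$mean_diff, -0.012, tolerance = 1e-12)
  expect_equal(r$summary$sd_diff, 0.047, tolerance = 1e-12)
  expect_equal(r$intervals$PI_bTI$lower, -0.11280144, tolerance = 1e-6)
  expect_equal(r$intervals$PI_bTI$upper, 0.08880144, tolerance = 1e-6)
  # both TIs exceed the +/- 0.1 band: equivalence not demonstrated
  expect_identical(r$decision, "not_demonstrated")
  # without an acceptance band there is no decision to make
  expect_identical(md_analyze(dog_sample())$decision, "not_assessed")
  # a generous band flips the decision
  r2 <- md_analyze(dog_sample(), gamma = 0.80,
                   acceptance = acceptance_spec(0.5))
  expect_identical(r2$decision, "equivalent")
})

test_that("acceptance bands follow their constant, percentage and step forms", {
  expect_equal(acceptance_band(acceptance_spec(10, percent = TRUE), 10)[1, ],
               c(lower = -1, upper = 1))
  expect_equal(acceptance_band(acceptance_spec(10, percent = TRUE), 20)[1, ],
               c(lower = -2, upper = 2))
  expect_equal(acceptance_band(acceptance_spec(0.1), 123)[1, ],
               c(lower = -0.1, upper = 0.1))
  step <- acceptance_spec(1, delta2 = 2, threshold = 15)
  expect_equal(acceptance_band(step, c(14.9, 15, 15.1))[, "upper"],
               c(1, 2, 2))  # delta2 applies at the threshold
  expect_error(acceptance_band(acceptance_spec(10, percent = TRUE), -1),
               "negative")
  expect_error(acceptance_spec(1, threshold = 5), "delta2")
})

test_that("decision is monotone in the acceptance width", {
  r_narrow <- md_analyze(dog_sample(), gamma = 0.8,
                         acceptance = acceptance_spec(0.05))
  widths <- c(0.11, 0.15, 0.5)
  decisions <- vapply(widths, function(d)
    md_analyze(dog_sample(), gamma = 0.8,
               acceptance = acceptance_spec(d))$decision, character(1))
  expect_identical(r_narrow$decision, "not_demonstrated")
  # once equivalent, enlarging the band never reverts the decision
  first_eq <- match("equivalent", decisions)
  expect_true(all(decisions[first_eq:length(decisions)] == "equivalent"))
})

test_that("pipeline is shift invariant and scale equivariant on the differences", {
  s <- dog_sample()
  a <- 2.5; b <- 10
  s2 <- paired_sample(a * s$x + b, a * s$y + b)
  r1 <- md_analyze(s, gamma = 0.9)
  r2 <- md_analyze(s2, gamma = 0.9)
  # common shift b cancels in D; scaling multiplies the bounds
  for (kind in c("AI", "PI_bTI", "bgTI_exact")) {
    expect_equal(r2$intervals[[kind]]$lower, a * r1$intervals[[kind]]$lower,
                 tolerance = 1e-9)
    expect_equal(r2$intervals[[kind]]$upper, a * r1$intervals[[kind]]$upper,
                 tolerance = 1e-9)
  }
})

test_that("log analysis back-transforms to the ratio scale consistently", {
  s <- lognormal_sample()
  r <- md_analyze(s, gamma = 0.8, transform = "log10",
                  acceptance = acceptance_spec(0.2, ratio_fraction = 0.2))
  ra <- antilog_intervals(r)
  expect_true(ra$back_transformed)
  # bounds are the antilogs of the log-scale bounds
  expect_equal(ra$intervals$PI_bTI$lower, 10^r$intervals$PI_bTI$lower,
               tolerance = 1e-12)
  expect_equal(ra$intervals$PI_bTI$upper, 10^r$intervals$PI_bTI$upper,
               tolerance = 1e-12)
  # round trip: log10 of the ratio bounds recovers the log-scale bounds
  expect_equal(log10(ra$intervals$bgTI_exact$lower),
               r$intervals$bgTI_exact$lower, tolerance = 1e-12)
  # geometric means on the x-axis
  expect_equal(ra$md$means, 10^r$md$means, tolerance = 1e-12)
  # the two decisions agree: the ratio band is the antilog of the log band
  expect_identical(r$decision, ra$decision)
  expect_error(antilog_intervals(ra), "already")
  expect_error(antilog_intervals(md_analyze(dog_sample())), "raw scale")
})

test_that("a 20% ratio tolerance gives acceptance bounds 0.8 and 1.25", {
  s <- lognormal_sample(log_mean = 0.01, log_sd = 0.02)
  r <- antilog_intervals(md_analyze(
    s, transform = "log10",
    acceptance = acceptance_spec(0.2, ratio_fraction = 0.2)))
  band <- c(1 - 0.2, 1 / (1 - 0.2))
  expect_identical(band, c(0.8, 1.25))
  # with tiny log-scale spread the TI sits inside (0.8, 1.25)
  expect_identical(r$decision, "equivalent")
  expect_gt(r$intervals$PI_bTI$lower, band[1])
  expect_lt(r$intervals$PI_bTI$upper, band[2])
})

test_that("normality check is advisory and handles degenerate input", {
  set.seed(10)
  d <- rnorm(100)
  expect_equal(normality_check(d), shapiro.test(d)$p.value,
               tolerance = 1e-6)
  expect_warning(p <- normality_check(rep(1, 10)), "constant")
  expect_true(is.na(p))
  expect_warning(p2 <- normality_check(c(1, 2)), "3 to 5000")
  expect_true(is.na(p2))
})

test_that("subjects with missing replicates are dropped with a report", {
  x <- c(1.2, NA, 3.1, 2.2)
  y <- c(1.1, 2.0, 3.0, 2.4)
  expect_message(s <- paired_sample(x, y), "1 subject")
  expect_equal(nrow(s$x), 3)
  expect_equal(s$n_dropped, 1L)
})
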