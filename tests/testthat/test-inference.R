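make_estimate <- function(value, rba, sex = "F", method = "lifetable",
                          def = "first", period = "2016",
                          ci = c(NA_real_, NA_real_)) {
  liferisk:::new_lifetime_risk_estimate(
    value = value, risk_by_age = rba, method = method,
    event_definition = def, sex = sex, period = period,
    ci_low = ci[1], ci_high = ci[2])
}

yearly_fixture <- function(values, years = seq(2016, by = 1,
                                               length.out = length(values))) {
  lapply(seq_along(values), function(i) {
    make_estimate(values[i], stats::setNames(c(values[i] / 2, values[i]),
                                             c("0-4", "5+")),
                  period = as.character(years[i]))
  })
}

test_that("average_years reproduces the hand-computed t-interval", {
  est <- average_years(yearly_fixture(c(60, 61, 62, 63)), level = 0.95)
  expect_equal(est$value, 61.5)
  # sd = 1.290994, t_{0.975,3} = 3.182446 -> half-width 2.054
  expect_equal(est$ci_low, 59.446, tolerance = 1e-4)
  expect_equal(est$ci_high, 63.554, tolerance = 1e-4)
  expect_equal(est$period, "2016-2019")

  # zero variance collapses the interval
  z <- average_years(yearly_fixture(rep(59.1, 4)))
  expect_equal(c(z$ci_low, z$value, z$ci_high), rep(59.1, 3))

  # permutation invariance in year order
  p <- average_years(yearly_fixture(c(63, 60, 62, 61),
                                    years = c(2019, 2016, 2018, 2017)))
  expect_equal(p$value, est$value)
  expect_equal(p$ci_low, est$ci_low)

  expect_error(average_years(yearly_fixture(60)), "at least 2")
  expect_error(average_years(yearly_fixture(c(60, 61)), level = 1.2),
               "in \\(0, 1\\)")
})

test_that("average_years CI width shrinks like 1/sqrt(k)", {
  # simulate yearly replicates with unit variance; compare mean widths
  set.seed(21)
  mean_width <- function(k, sims = 400) {
    mean(replicate(sims, {
      e <- average_years(yearly_fixture(stats::rnorm(k, 60, 1)))
      e$ci_high - e$ci_low
    }))
  }
  c4 <- function(n) sqrt(2 / (n - 1)) * gamma(n / 2) / gamma((n - 1) / 2)
  expected_ratio <- (stats::qt(0.975, 3) * c4(4) / sqrt(4)) /
    (stats::qt(0.975, 15) * c4(16) / sqrt(16))
  expect_equal(mean_width(4) / mean_width(16), expected_ratio,
               tolerance = 0.1)
})

test_that("single-year bootstrap CI is deterministic and concentrates", {
  s <- two_band_schema()
  tabs <- small_tables(s, all_events = 80, first_events = 50,
                       population = 1000, deaths = 20)
  args <- list(tabs$events, tabs$population, tabs$deaths, year = 2016,
               sex = "F", schema = s, reps = 1000)
  a <- do.call(single_year_ci, c(args, seed = 7))
  b <- do.call(single_year_ci, c(args, seed = 7))
  expect_identical(a$ci_low, b$ci_low)
  expect_identical(a$ci_high, b$ci_high)
  c2 <- do.call(single_year_ci, c(args, seed = 8))
  expect_false(identical(a$ci_low, c2$ci_low))

  big <- small_tables(s, all_events = 8000, first_events = 5000,
                      population = 100000, deaths = 2000)
  d <- single_year_ci(big$events, big$population, big$deaths, 2016, "F",
                      schema = s, reps = 1000, seed = 7)
  expect_lt(d$ci_high - d$ci_low, a$ci_high - a$ci_low)

  zero <- small_tables(s, all_events = 0, first_events = 0,
                       population = 1000, deaths = 0)
  w <- testthat::capture_warnings(
    z <- single_year_ci(zero$events, zero$population, zero$deaths, 2016, "F",
                        schema = s, reps = 1000))
  expect_match(w, "degenerate", all = FALSE)
  expect_equal(c(z$ci_low, z$ci_high), c(0, 0))
  expect_error(do.call(single_year_ci, c(args[1:5], reps = 10)), ">= 1000")
})

test_that("compare_periods matches the hand-computed paired t-test", {
  pre <- make_estimate(30, stats::setNames(c(10, 20, 30), letters[1:3]))
  post <- make_estimate(27, stats::setNames(c(8, 19, 27), letters[1:3]))
  cmp <- compare_periods(pre, post)
  expect_equal(cmp$absolute_change, 3)
  expect_equal(cmp$relative_change, 10)
  expect_equal(cmp$t_statistic, 3.4641, tolerance = 1e-4)
  expect_equal(cmp$df, 2L)
  expect_equal(cmp$p_value, 0.0742, tolerance = 1e-3)
  # cross-check: paired t equals one-sample t on the differences
  one <- stats::t.test(pre$risk_by_age - post$risk_by_age)
  expect_equal(cmp$t_statistic, unname(one$statistic))
  expect_equal(cmp$p_value, one$p.value)

  expect_warning(same <- compare_periods(pre, pre), "zero-variance")
  expect_equal(same$absolute_change, 0)
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)
})

test_that("relative change recovers a known proportional decrease", {
  for (r in c(0.05, 0.2, 0.9)) {
    pre <- make_estimate(64, stats::setNames(c(32, 64), c("a", "b")))
    post <- make_estimate(64 * (1 - r),
                          stats::setNames(c(30, 64 * (1 - r)), c("a", "b")))
    expect_equal(compare_periods(pre, post)$relative_change, 100 * r)
  }
})

test_that("ci overlap is detected from interval intersection", {
  pre <- make_estimate(60, stats::setNames(c(30, 60), c("a", "b")),
                       ci = c(55, 65))
  post <- make_estimate(40, stats::setNames(c(20, 40), c("a", "b")),
                        ci = c(39, 42))
  expect_false(compare_periods(pre, post)$ci_overlap)
  post2 <- make_estimate(56, stats::setNames(c(20, 56), c("a", "b")),
                         ci = c(54, 58))
  expect_true(compare_periods(pre, post2)$ci_overlap)
})

test_that("max successive increase finds the steepest step, ties to older", {
  rba <- stats::setNames(c(1, 3, 6, 6.5), paste0("b", 1:4))
  got <- max_successive_increase(rba)
  expect_equal(got$from_band, "b2")
  expect_equal(got$increase, 3)
  expect_equal(max_successive_increase(
    stats::setNames(rep(5, 4), paste0("b", 1:4)))$increase, 0)
  # exact tie: prefer the older pair
  tie <- stats::setNames(c(0, 2, 4, 5), paste0("b", 1:4))
  expect_equal(max_successive_increase(tie)$from_band, "b2")
  expect_error(max_successive_increase(stats::setNames(1, "x")), "2 bands")
})

test_that("sex difference is the band-wise F minus M gap", {
  f <- make_estimate(60, stats::setNames(c(30, 60), c("a", "b")), sex = "F")
  m <- make_estimate(59, stats::setNames(c(28, 59), c("a", "b")), sex = "M")
  expect_equal(sex_difference(f, m, "a"), 2)
  expect_equal(sex_difference(m, f, "a"), -2)  # antisymmetric
  expect_equal(sex_difference(f, f, "a"), 0)
  expect_error(sex_difference(f, m, "zz"), "absent")
})

test_that("round_half_up rounds ties away from zero", {
  expect_equal(round_half_up(5.75, 1), 5.8)
  expect_equal(round_half_up(5.75), 6)
  expect_equal(round_half_up(-5.75), -6)
  expect_equal(round_half_up(2.5), 3)  # unlike base round()
})
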