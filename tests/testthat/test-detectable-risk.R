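test_that("power at the null equals one rejection tail", {
  expect_equal(power_two_proportions(0.1, 500, 0.1, 500), 0.025,
               tolerance = 1e-12)
  expect_equal(power_two_proportions(0.1, 500, 0.1, 500, alpha = 0.10), 0.05,
               tolerance = 1e-12)
  expect_error(power_two_proportions(0, 10, 0.5, 10), "degenerate")
  expect_error(power_two_proportions(0.5, 10, 1, 10), "degenerate")
})

test_that("power increases in effect size and sample size", {
  p1 <- seq(0.26, 0.36, by = 0.01)
  pw <- power_two_proportions(p1, 1000, 0.25, 1000)
  expect_true(all(diff(pw) > 0))
  pw_n <- vapply(c(100, 400, 1600), function(n) {
    power_two_proportions(0.3, n, 0.25, 3 * n)
  }, numeric(1))
  expect_true(all(diff(pw_n) > 0))
})

test_that("large two-year cohorts make a 1.2x effect all but certain", {
  expect_gte(power_two_proportions(0.30, 4842, 0.25, 4842), 0.999)
})

test_that("detectable RR point satisfies the bisection bracket", {
  res <- min_detectable_rr_cohort(500, 5000)
  d <- design_assumptions()
  p0 <- 0.1
  total <- 5000 * 2
  pw <- function(rr) power_two_proportions(rr * p0, total / 4, p0,
                                           3 * total / 4)
  tol <- 1e-6
  expect_lt(pw(res$point - 2 * tol), d$target_power)
  expect_gte(pw(res$point + 2 * tol), d$target_power)
  expect_gte(res$point, 1)
  expect_true(res$ci_low <= res$point && res$point <= res$ci_high)
})

test_that("detectable RR shrinks toward 1 as the cohort grows", {
  points <- vapply(c(1e4, 1e5, 1e6, 1e7), function(annual) {
    min_detectable_rr_cohort(100, 1000, annual_denominator = annual)$point
  }, numeric(1))
  expect_true(all(diff(points) < 0))
  expect_lt(points[4], 1.01)
})

test_that("odds-ratio exposure mapping has the right limits", {
  expect_equal(perisurv:::case_exposure_prob(1, 0.25), 0.25)
  expect_gt(perisurv:::case_exposure_prob(1e6, 0.25), 0.999)
  expect_lt(perisurv:::case_exposure_prob(1.0001, 0.25) - 0.25, 1e-4)
})

test_that("zero events admit no finite detectable risk", {
  expect_error(min_detectable_rr_cohort(0, 1000), "no finite")
  expect_error(min_detectable_or_case_control(0, 1000), "no finite")
})

test_that("confidence bounds propagate the rate interval with the right orientation", {
  res_rr <- min_detectable_rr_cohort(50, 5000)
  res_or <- min_detectable_or_case_control(50, 5000)
  for (res in list(res_rr, res_or)) {
    expect_lt(res$ci_low, res$point)
    expect_gt(res$ci_high, res$point)
  }
  # a higher baseline rate gives a smaller detectable effect
  lo_rate <- min_detectable_rr_cohort(25, 5000)
  expect_gt(lo_rate$point, res_rr$point)
})

test_that("bisection agrees with an exhaustive grid-search oracle", {
  grid_oracle <- function(power_fn, target, step = 1e-3) {
    grid <- seq(1 + step, 20, by = step)
    pw <- vapply(grid, power_fn, numeric(1))
    grid[which(pw >= target)[1]]
  }
  set.seed(13)
  d <- design_assumptions()
  for (i in 1:10) {
    n <- sample(2000:10000, 1)
    x <- rbinom(1, n, runif(1, 0.02, 0.3))
    res <- min_detectable_rr_cohort(x, n)
    p0 <- x / n
    oracle <- grid_oracle(function(rr) {
      if (rr * p0 >= 1) return(1)
      power_two_proportions(rr * p0, n * 2 / 4, p0, 3 * n * 2 / 4)
    }, d$target_power)
    expect_lt(abs(res$point - oracle), 1e-3 + 1e-6)
    res_or <- min_detectable_or_case_control(x, n)
    cases <- p0 * n * 2
    oracle_or <- grid_oracle(function(or) {
      power_two_proportions(perisurv:::case_exposure_prob(or, 0.25), cases,
                            0.25, cases)
    }, d$target_power)
    expect_lt(abs(res_or$point - oracle_or), 1e-3 + 1e-6)
  }
})

test_that("scenario grids are consistent, ordered and monotone", {
  single <- scenario_grid(500, 5000, durations = 2, exposed_ratios = 3,
                          control_ratios = 1, coverages = 0.25)
  expect_equal(nrow(single), 2)
  expect_equal(single$point[single$measure == "relative_risk"],
               min_detectable_rr_cohort(500, 5000)$point)
  expect_equal(single$point[single$measure == "odds_ratio"],
               min_detectable_or_case_control(500, 5000)$point)

  grid <- scenario_grid(500, 5000, durations = c(1, 2, 4),
                        exposed_ratios = 3, measures = "relative_risk")
  expect_true(all(diff(grid$point) < 0))  # longer accrual, smaller MDR

  balanced <- scenario_grid(500, 5000, durations = 2,
                            exposed_ratios = c(1, 3),
                            measures = "relative_risk")
  expect_lte(balanced$point[balanced$cohort_exposed_ratio == 1],
             balanced$point[balanced$cohort_exposed_ratio == 3])
  expect_error(scenario_grid(500, 5000, durations = numeric()), "non-empty")
})
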