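test_that("target levels are the sex/age-group maxima over FPL categories", {
  tab <- fix_table()
  expect_equal(target_level(tab, "male", "6-10"), 4.39)
  expect_equal(round(target_level(tab, "male", "6-10"), 1), 4.4)
  expect_equal(target_level(tab, "female", "14-17"), 3.01)

  # the target is attained by the >=400% FPL stratum in all six groups
  for (sx in c("male", "female")) {
    for (ab in c("6-10", "11-13", "14-17")) {
      i <- paequity:::stratum_row(tab, sx, ab, ">=400%")
      expect_equal(target_level(tab, sx, ab), tab$pa_days_mean[i])
    }
  }
})

test_that("disparity reduction shifts means linearly, upward only", {
  tab <- fix_table()
  coh <- fix_cohort(2400)

  same <- apply_reduction(coh, tab, scenario_spec(0))
  expect_identical(same$pa_days_mean, coh$pa_days_mean)

  sel <- coh$sex == "female" & coh$age_band == "14-17" & coh$fpl == "<100%"
  full <- apply_reduction(coh, tab, scenario_spec(1))
  expect_equal(full$pa_days_mean[sel],
               pmin(coh$pa_days_mean[sel] + (3.01 - 2.64), 7))  # shift +0.37, capped at 7
  half <- apply_reduction(coh, tab, scenario_spec(0.5))
  expect_equal(half$pa_days_mean[sel],
               pmin(coh$pa_days_mean[sel] + 0.5 * (3.01 - 2.64), 7))

  # top stratum unchanged at any r; nobody ever shifts down
  top <- coh$fpl == ">=400%"
  for (r in c(0.25, 0.6, 1)) {
    sh <- apply_reduction(coh, tab, scenario_spec(r))
    expect_identical(sh$pa_days_mean[top], coh$pa_days_mean[top])
    expect_true(all(sh$pa_days_mean >= coh$pa_days_mean - 1e-12))
  }
})

test_that("weekly draws are bounded, mean-matching, and seed-deterministic", {
  sp <- scenario_spec(1)
  expect_identical(draw_week(7, sp, u = 0.5)$active_days, 7L)

  set.seed(404)
  d <- draw_week(rep(3.26, 10000), sp)
  expect_true(all(d$active_days >= 0 & d$active_days <= 7))
  expect_lt(abs(mean(d$active_days) - 3.26), 0.05)

  u <- runif(50)
  expect_identical(draw_week(rep(2.5, 50), sp, u), draw_week(rep(2.5, 50), sp, u))

  # bounds hold for any mean in [0, 7]
  for (m in seq(0, 7, by = 0.5)) {
    a <- draw_week(rep(m, 200), sp)$active_days
    expect_true(all(a >= 0 & a <= 7))
  }
})

test_that("active-day expectation is non-decreasing in r under common random numbers", {
  tab <- fix_table()
  coh <- fix_cohort(2400)
  set.seed(77)
  u <- stats::runif(nrow(coh))
  prev <- rep(-Inf, nrow(coh))
  for (r in c(0, 0.25, 0.5, 0.75, 1)) {
    m <- apply_reduction(coh, tab, scenario_spec(r))$pa_days_mean
    a <- draw_week(m, scenario_spec(r), u)$active_days
    expect_true(all(a >= prev))
    prev <- a
  }
})

test_that("intake adjustment implements the three compensation modes", {
  none <- scenario_spec(1, compensation_mode = "none")
  expect_equal(intake_adjustment(c(0, 200), 2000, none), c(0, 0))

  half <- scenario_spec(1, compensation_mode = "fraction_of_extra",
                        compensation_value = 0.5)
  expect_equal(intake_adjustment(200, 2000, half), 100)

  diet <- scenario_spec(1, compensation_mode = "diet_improvement")
  expect_equal(intake_adjustment(c(0, 500), 2000, diet), c(-40, -40))

  expect_error(scenario_spec(1, compensation_mode = "fraction_of_extra",
                             compensation_value = 1.5), "\\[0, 1\\]")
  expect_error(intake_adjustment(-5, 2000, none))
})
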