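test_that("daily energy expenditure is additive and monotone in MVPA", {
  p <- metabolic_params()
  ee0 <- daily_energy_expenditure(50, 38, 0, "male", p)
  expect_equal(ee0, p$rmr_intercept[["male"]] + p$rmr_slope * 38 + p$offday_activity)

  # default net cost 0.1 kcal/kg/min: 50 kg x 30 min -> +150 kcal
  expect_equal(daily_energy_expenditure(50, 38, 30, "male", p) - ee0, 150)

  grid <- daily_energy_expenditure(50, 38, seq(0, 120, by = 5), "male", p)
  expect_true(all(diff(grid) > 0))
})

test_that("daily update conserves energy and respects units", {
  gr <- fix_growth()
  ag <- fix_cohort(2400)[3, ]

  # surplus 0: weight (mass) unchanged exactly
  ee <- daily_energy_expenditure(ag$weight_kg, ag$fat_free_mass, 45, ag$sex)
  up <- daily_update(ag, list(mvpa_minutes = 45, intake_kcal = ee), gr)
  expect_equal(up$weight_kg, ag$weight_kg)
  expect_equal(up$age_days, ag$age_days + 1L)

  # +7700 kcal with 100% fat partition at 7700 kcal/kg -> exactly +1 kg fat
  p2 <- metabolic_params(fat_partition = 1, energy_density_fat = 7700)
  up2 <- daily_update(ag, list(mvpa_minutes = 0,
                               intake_kcal = ee + 7700 - 0.1 * ag$weight_kg * 45),
                      gr, p2)
  expect_equal(up2$fat_mass - ag$fat_mass, 1)
  expect_equal(up2$fat_free_mass, ag$fat_free_mass)
})

test_that("365 daily updates match a brute-force reference trajectory", {
  gr <- fix_growth()
  p <- metabolic_params()
  ag <- fix_cohort(2400)[10, ]
  set.seed(21)
  intakes <- runif(365, 1200, 2600)
  minutes <- sample(c(0, 30, 60), 365, TRUE)

  # package path
  a <- ag
  for (t in 1:365) {
    a <- daily_update(a, list(mvpa_minutes = minutes[t], intake_kcal = intakes[t]), gr, p)
  }

  # independent single-loop reference (no package update code)
  fat <- ag$fat_mass; ffm <- ag$fat_free_mass; ad <- ag$age_days
  sxi <- if (ag$sex == "male") 1 else 2
  cum_surplus <- 0
  for (t in 1:365) {
    ee <- p$rmr_intercept[[sxi]] + p$rmr_slope * ffm + p$offday_activity +
      p$mvpa_net_cost * (fat + ffm) * minutes[t]
    s <- intakes[t] - ee
    cum_surplus <- cum_surplus + s
    fat <- fat + p$fat_partition * s / p$energy_density_fat
    ffm <- ffm + (1 - p$fat_partition) * s / p$energy_density_ffm
    ad <- ad + 1L
  }
  expect_equal(a$fat_mass, fat, tolerance = 1e-12)
  expect_equal(a$fat_free_mass, ffm, tolerance = 1e-12)

  # energy conservation: mass change x densities == cumulative surplus
  lhs <- (a$fat_mass - ag$fat_mass) * p$energy_density_fat +
    (a$fat_free_mass - ag$fat_free_mass) * p$energy_density_ffm
  expect_equal(lhs, cum_surplus, tolerance = 1e-6)
})

test_that("the rolling calibration policy holds BMI percentile; deficits shed weight", {
  gr <- fix_growth()
  p <- metabolic_params()
  coh <- fix_cohort(2400)[c(2, 800, 1600, 2300), ]
  coh <- coh[coh$age_days < 6000, ]
  intake <- calibrate_intake(coh, gr, p)
  expect_identical(intake, calibrate_intake(coh, gr, p))
  expect_true(all(intake > 500 & intake < 6000))

  # closed-loop self-check: one year under the maintenance policy
  p0 <- coh$bmi_percentile_at_baseline
  base <- roll_sim(coh, gr, p, 365)
  expect_lt(max(abs(base$pct - p0)), 1)

  # raising PA with the intake schedule frozen -> weight below baseline
  more <- roll_sim(coh, gr, p, 365, extra_min = 15,
                   frozen_intakes = base$intakes)
  expect_true(all(more$weight < base$weight))
})

test_that("final weight at 18 is non-increasing in added daily MVPA at fixed intake", {
  gr <- fix_growth()
  p <- metabolic_params()
  coh <- fix_cohort(2400)[c(5, 1200), ]
  days <- max(6574L - coh$age_days)
  base <- roll_sim(coh, gr, p, days)
  final_w <- sapply(c(0, 10, 20, 30), function(extra) {
    roll_sim(coh, gr, p, days, extra_min = extra,
             frozen_intakes = base$intakes)$weight
  })
  expect_true(all(apply(final_w, 1, function(x) all(diff(x) < 0))))
})

test_that("calibration fails with a diagnostic when no root exists", {
  gr <- fix_growth()
  hungry <- metabolic_params(rmr_slope = 300)  # RMR alone exceeds 6000 kcal
  expect_error(calibrate_intake(fix_cohort(2400)[1, ], gr, hungry),
               "no maintenance intake")
})
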