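test_that("productivity loss is the wage-presenteeism product", {
  expect_equal(productivity_loss(100, 1.0, 250), 0)
  expect_equal(productivity_loss(200, 0.8, 10), 400)
  expect_equal(productivity_loss(300, 0.5, 0), 0)
  expect_error(productivity_loss(100, 1.2, 10), "\\[0, 1\\]")
})

test_that("discounting matches the closed-form geometric series", {
  ec <- econ_params(discount_rate = 0.03)
  expect_equal(discount(500, 0, ec), 500)
  expect_equal(discount(103, 1, ec), 100)

  # 30-year unit annuity vs closed form
  got <- sum(discount(rep(1, 30), 0:29, ec))
  want <- (1 - 1.03^-30) / 0.03 * 1.03  # annuity-due
  expect_equal(got, want, tolerance = 1e-9)

  ec0 <- econ_params(discount_rate = 0)
  expect_equal(discount(c(5, 7), c(3, 40), ec0), c(5, 7))
})

test_that("summarize_econ maps a life course to discounted accruals", {
  mp <- degenerate_markov()
  # constant-state, no-event record for 30 years
  rec <- run_lifecourse(1L, "male", mp, seed = 3, max_age = 47)

  ec0 <- econ_params(discount_rate = 0)
  s0 <- summarize_econ(rec, mp, ec0)
  yrs <- rec$life_years
  expect_equal(s0$life_years, 30L)
  expect_equal(s0$qalys, yrs * unname(mp$utility[1]))
  expect_equal(s0$direct_usd,
               sum(mp$state_cost[1, pmin(1:yrs, length(mp$ages)), 1]))

  # discounted single-state constant-cost record vs hand annuity
  mp2 <- mp
  mp2$state_cost[1, , 1] <- 1000
  ec <- econ_params(discount_rate = 0.03)
  s <- summarize_econ(rec, mp2, ec)
  expect_equal(s$direct_usd, 1000 * (1 - 1.03^-30) / 0.03 * 1.03, tolerance = 1e-9)

  # payer <= societal for any record
  ep <- econ_params(perspective = "payer")
  expect_lte(summarize_econ(rec, fix_markov(), ep)$total_usd,
             summarize_econ(rec, fix_markov(), econ_params())$total_usd)

  # dead at entry: zero accruals
  doom <- mp
  doom$P[] <- 0
  doom$P[, doom$death_state, , ] <- 1
  doom$P[doom$death_state, , , ] <- 0
  doom$P[doom$death_state, doom$death_state, , ] <- 1
  dead <- run_lifecourse(1L, "male", doom, seed = 1)
  sd0 <- summarize_econ(dead, mp, ec)
  expect_equal(sd0$direct_usd + sd0$productivity_usd + sd0$qalys, 0)

  # constant positive annual cost: undiscounted cost increases with life-years
  longer <- run_lifecourse(1L, "male", mp2, seed = 3, max_age = 60)
  expect_gt(summarize_econ(longer, mp2, ec0)$direct_usd,
            summarize_econ(rec, mp2, ec0)$direct_usd)

  # discounting strictly decreases totals as the rate rises
  r_grid <- c(0, 0.02, 0.05)
  tots <- sapply(r_grid, function(r) {
    summarize_econ(rec, mp2, econ_params(discount_rate = r))$total_usd
  })
  expect_true(all(diff(tots) < 0))
})
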