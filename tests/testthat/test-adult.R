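test_that("entry state depends only on the BMI category at 18", {
  mp <- fix_markov()
  expect_equal(entry_state("normal", mp), 1L)
  expect_equal(entry_state("overweight", mp), 5L)
  expect_equal(entry_state("obese", mp), 9L)
  # two agents, same final category, different final weights: same entry state
  expect_equal(entry_state(c("obese", "obese"), mp), c(9L, 9L))
  classes <- c("normal", "overweight", "obese")
  expect_true(all(grepl("healthy", mp$states[entry_state(classes, mp)])))
  expect_error(entry_state("chunky", mp), "invalid weight class")
})

test_that("step_year is absorbing at death and inert under identity dynamics", {
  mp <- degenerate_markov()
  rec <- lifecourse_record(entry_state("normal", mp), "male")
  rec$alive <- FALSE
  rec$state <- mp$death_state
  expect_identical(step_year(rec, mp), rec)

  rec2 <- run_lifecourse(entry_state("overweight", mp), "female", mp, seed = 5,
                         max_age = 97)
  expect_true(rec2$censored)
  expect_equal(rec2$life_years, 80L)
  expect_true(all(rec2$path$state == 5L))
  expect_equal(sum(rec2$events_total), 0L)

  bad <- fix_markov()
  bad$P[1, 1, 1, 1] <- bad$P[1, 1, 1, 1] + 0.5
  expect_error(step_year(lifecourse_record(1L, "male"), bad), "malformed transition row")
})

test_that("single-step transition frequencies match the row probabilities", {
  mp <- fix_markov()
  n <- 20000
  set.seed(99)
  states <- integer(n)
  for (i in seq_len(n)) {
    r <- step_year(lifecourse_record(9L, "male"), mp)
    states[i] <- r$state
  }
  row <- mp$P[9, , 1, 1]
  # the record can land on death either via the row or via event fatality;
  # check the living states the row can reach
  for (s in which(row > 1e-6 & seq_along(row) != mp$death_state)) {
    se <- sqrt(row[s] * (1 - row[s]) / n)
    # event fatality moves a small share of each living state to death
    expect_lt(abs(mean(states == s) - row[s]), 3 * se + 0.01)
  }
})

test_that("lifecourse replays are deterministic and die immediately under certain death", {
  mp <- fix_markov()
  a <- run_lifecourse(9L, "male", mp, seed = 123)
  b <- run_lifecourse(9L, "male", mp, seed = 123)
  expect_identical(a, b)
  expect_true(all(a$deaths_cause <= as.integer(!a$alive)))
  expect_true(all(a$events_total == floor(a$events_total)))

  doom <- degenerate_markov()
  doom$P[] <- 0
  doom$P[, doom$death_state, , ] <- 1
  doom$P[doom$death_state, , , ] <- 0
  doom$P[doom$death_state, doom$death_state, , ] <- 1
  rec <- run_lifecourse(1L, "male", doom, seed = 1)
  expect_equal(rec$life_years, 0L)
  expect_false(rec$alive)
})

test_that("simulated state occupancy matches the matrix-product oracle", {
  mp <- fix_markov()
  ec <- econ_params()
  n <- 30000
  sim <- paequity:::simulate_adult_cohort(rep(5L, n), rep(2L, n), mp, ec, seed = 8)
  occ <- markov_occupancy(5L, "female", mp)
  emp <- sim$occupancy / n
  for (a in c(5, 20, 40, 60, 82)) {
    p <- occ[a, ]
    se <- sqrt(p * (1 - p) / n)
    live <- p > 1e-5 & p < 1 - 1e-5
    expect_true(all(abs(emp[a, live] - p[live]) < 3 * se[live] + 1e-9),
                label = paste("occupancy at year", a))
  }
  expect_equal(rowSums(occ), rep(1, nrow(occ)), tolerance = 1e-9)
})

test_that("lifetime event risk is non-decreasing across entry BMI category", {
  mp <- fix_markov()
  ea <- paequity:::expected_adult_outcomes(mp, econ_params())
  for (sx in c("male", "female")) {
    for (k in paste0("events_", c("chd", "stroke", "t2d", "cancer"))) {
      v <- ea[, sx, k]
      expect_true(all(diff(v) >= 0), label = paste(sx, k))
    }
    expect_true(all(diff(ea[, sx, "deaths_total"]) >= 0))
  }
})
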