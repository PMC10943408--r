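test_that("agents are allocated to strata by largest-remainder apportionment", {
  tab <- fix_table()
  coh <- fix_cohort(24000)
  got <- as.vector(table(factor(coh$stratum, levels = 1:24)))

  # independent oracle: re-derive Hamilton apportionment from first principles
  q <- 24000 * tab$population / sum(tab$population)
  base <- floor(q)
  ord <- order(-(q - base), seq_along(q))
  extra <- ord[seq_len(24000 - sum(base))]
  base[extra] <- base[extra] + 1
  expect_identical(got, as.integer(base))

  # printed-arithmetic example: (male, 6-10, <100%) gets ~947 of 24 000
  i <- paequity:::stratum_row(tab, "male", "6-10", "<100%")
  expect_lte(abs(got[i] - 24000 * tab$population[i] / sum(tab$population)), 1)
})

test_that("sampling weights reconstruct the national population exactly", {
  coh <- fix_cohort(2400)
  expect_equal(sum(coh$sampling_weight), sum(fix_table()$population))
  by_str <- rowsum(coh$sampling_weight, coh$stratum)
  expect_equal(as.vector(by_str), as.numeric(fix_table()$population))
})

test_that("stratum PA means and prevalence are recovered in expectation", {
  tab <- fix_table()
  coh <- fix_cohort(30000, seed = 11)
  i <- paequity:::stratum_row(tab, "female", "14-17", "<100%")
  sel <- coh$stratum == i
  n <- sum(sel)
  se <- 1.5 / sqrt(n)
  expect_lt(abs(mean(coh$pa_days_mean[sel]) - 2.64), 3 * se)

  p <- (tab$overweight_prev[i] + tab$obesity_prev[i]) / 100
  se_p <- sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(coh$weight_class[sel] != "normal") - p), 3 * se_p)

  expect_true(all(coh$pa_days_mean >= 0 & coh$pa_days_mean <= 7))
  expect_equal(coh$weight_kg, coh$fat_mass + coh$fat_free_mass)
  expect_equal(coh$bmi, coh$weight_kg / (coh$height_cm / 100)^2)
})

test_that("n_agents too small to cover all strata fails, listing empty strata", {
  skew <- fix_table()
  skew$population[1] <- 1e9  # one stratum swallows the whole allocation
  class(skew) <- class(fix_table())
  expect_error(build_cohort(skew, fix_growth(), cohort_spec(30, seed = 1)),
               "empty strata")
})

test_that("weight classification uses half-open 85/95 percentile bands", {
  gr <- fix_growth()
  age <- 4000L
  t85 <- unname(gr$bmi_p85[paequity:::growth_idx(gr, age), 1])
  t95 <- unname(gr$bmi_p95[paequity:::growth_idx(gr, age), 1])
  expect_identical(classify_weight(t85, "male", age, gr), "overweight")
  expect_identical(classify_weight(t95, "male", age, gr), "obese")
  expect_identical(classify_weight(t85 - 1e-9, "male", age, gr), "normal")
  expect_identical(classify_weight(12, "male", age, gr), "normal")
  expect_error(classify_weight(20, "male", 1000, gr), "age outside")
})

test_that("classification agrees with a brute-force threshold comparison", {
  gr <- fix_growth()
  set.seed(31)
  n <- 1000
  sex <- sample(c("male", "female"), n, TRUE)
  age <- sample(2192:6574, n, TRUE)
  bmi <- runif(n, 12, 40)
  got <- classify_weight(bmi, sex, age, gr)
  # brute force, agent by agent
  want <- vapply(seq_len(n), function(i) {
    k <- paequity:::growth_idx(gr, age[i])
    sx <- if (sex[i] == "male") 1 else 2
    if (bmi[i] >= gr$bmi_p95[k, sx]) "obese"
    else if (bmi[i] >= gr$bmi_p85[k, sx]) "overweight"
    else "normal"
  }, character(1))
  expect_identical(got, want)
})
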