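#' Metabolic (energy-balance) parameters
#'
#' Daily energy budget: resting metabolic rate is affine in fat-free mass
#' (Cunningham-style, sex-specific intercept); non-MVPA activity is a flat
#' daily allowance; MVPA costs a net (above-rest) `mvpa_net_cost` kcal per kg
#' body weight per minute (default 0.1, roughly a 4-5 MET activity net of
#' rest).  A caloric surplus or deficit is partitioned 75\% to fat mass and
#' 25\% to fat-free mass and converted with tissue energy densities 9441 and
#' 1816 kcal/kg -- a fixed-partition approximation to dynamic energy-balance
#' models, declared as such.
#'
#' @param rmr_intercept Named kcal/day intercepts for `male`/`female`.
#' @param rmr_slope kcal/day per kg fat-free mass.
#' @param offday_activity Non-MVPA activity allowance, kcal/day.
#' @param mvpa_net_cost kcal/kg/min above rest during MVPA.
#' @param fat_partition Fraction of any surplus (or deficit) routed to fat.
#' @param energy_density_fat,energy_density_ffm kcal per kg of tissue.
#' @param min_fat,min_ffm Mass floors, kg (clamped with a warning counter).
#' @return A `metabolic_params` list.
#' @export
metabolic_params <- function(rmr_intercept = c(male = 520, female = 480),
                             rmr_slope = 22, offday_activity = 400,
                             mvpa_net_cost = 0.1, fat_partition = 0.75,
                             energy_density_fat = 9441,
                             energy_density_ffm = 1816,
                             min_fat = 2, min_ffm = 10) {
  stopifnot(all(rmr_intercept > 0), rmr_slope > 0, offday_activity >= 0,
            mvpa_net_cost > 0, fat_partition >= 0, fat_partition <= 1,
            energy_density_fat > 0, energy_density_ffm > 0)
  p <- list(rmr_intercept = rmr_intercept, rmr_slope = rmr_slope,
            offday_activity = offday_activity, mvpa_net_cost = mvpa_net_cost,
            fat_partition = fat_partition,
            energy_density_fat = energy_density_fat,
            energy_density_ffm = energy_density_ffm,
            min_fat = min_fat, min_ffm = min_ffm)
  # kg of mass change per kcal of surplus under the fixed partition
  p$mass_per_kcal <- p$fat_partition / p$energy_density_fat +
    (1 - p$fat_partition) / p$energy_density_ffm
  class(p) <- "metabolic_params"
  p
}

#' Daily energy expenditure
#'
#' `EE = RMR(fat-free mass) + off-day activity allowance +
#'  mvpa_net_cost x weight x MVPA minutes` (kcal/day).  Vectorized.
#'
#' @param weight_kg,fat_free_mass Body masses, kg.
#' @param mvpa_minutes Minutes of MVPA today.
#' @param sex `"male"`/`"female"` (recycled).
#' @param params A `metabolic_params`.
#' @return kcal/day.
#' @export
daily_energy_expenditure <- function(weight_kg, fat_free_mass, mvpa_minutes,
                                     sex, params = metabolic_params()) {
  sexi <- match(sex, SEX_LEVELS)
  unname(params$rmr_intercept[sexi]) + params$rmr_slope * fat_free_mass +
    params$offday_activity +
    params$mvpa_net_cost * weight_kg * mvpa_minutes
}

#' One daily energy-balance update
#'
#' Advances height one day along the growth reference, computes the caloric
#' surplus `intake - EE` for the day's plan, partitions it into fat and
#' fat-free mass change, and recomputes BMI.  Vectorized over agents.
#'
#' @param agent Data frame with `sex`, `age_days`, `height_cm`, `fat_mass`,
#'   `fat_free_mass` (a `cohort` works).
#' @param plan List with `mvpa_minutes` and `intake_kcal`.
#' @param growth A `growth_reference`.
#' @param params A `metabolic_params`.
#' @return `agent` one day older with updated masses, height, `weight_kg`,
#'   `bmi`.
#' @export
daily_update <- function(agent, plan, growth, params = metabolic_params()) {
  if (any(agent$age_days >= AGE_MAX_DAYS)) {
    stop("daily_update: agent already at or beyond age 18", call. = FALSE)
  }
  sexi <- match(agent$sex, SEX_LEVELS)
  ee <- daily_energy_expenditure(agent$fat_mass + agent$fat_free_mass,
                                 agent$fat_free_mass, plan$mvpa_minutes,
                                 agent$sex, params)
  surplus <- plan$intake_kcal - ee
  fat <- agent$fat_mass + params$fat_partition * surplus / params$energy_density_fat
  ffm <- agent$fat_free_mass +
    (1 - params$fat_partition) * surplus / params$energy_density_ffm
  clamped <- fat < params$min_fat | ffm < params$min_ffm
  if (any(clamped)) {
    warning(sum(clamped), " agent-day mass updates clamped at the floor")
    fat <- pmax(fat, params$min_fat)
    ffm <- pmax(ffm, params$min_ffm)
  }
  agent$age_days <- agent$age_days + 1L
  k <- cbind(growth_idx(growth, agent$age_days), sexi)
  # height advances along the reference velocity at the agent's age
  agent$height_cm <- agent$height_cm +
    growth$velocity_cm[cbind(growth_idx(growth, agent$age_days - 1L), sexi)]
  agent$fat_mass <- fat
  agent$fat_free_mass <- ffm
  agent$weight_kg <- fat + ffm
  agent$bmi <- agent$weight_kg / (agent$height_cm / 100)^2
  agent
}

# Expected daily MVPA minutes at a weekly mean of `m` active days.
expected_mvpa_minutes <- function(m, offday_minutes) {
  (m * 60 + (7 - m) * offday_minutes) / 7
}

#' Calibrate maintenance caloric intake
#'
#' Finds, for each agent, the constant daily intake under which a 28-day
#' forward simulation at the agent's expected baseline PA leaves its BMI
#' percentile within `tol` (default 0.1) percentile points of baseline
#' (bisection on intake; drift is monotone in intake).
#'
#' @param cohort A `cohort` (or compatible data.frame).
#' @param growth A `growth_reference`.
#' @param params A `metabolic_params`.
#' @param offday_minutes Minutes of PA on non-active days (default 30).
#' @param tol Percentile drift tolerance.
#' @return kcal/day per agent.
#' @export
calibrate_intake <- function(cohort, growth, params = metabolic_params(),
                             offday_minutes = 30, tol = 0.1) {
  sexi <- match(cohort$sex, SEX_LEVELS)
  em <- expected_mvpa_minutes(cohort$pa_days_mean, offday_minutes)
  p0 <- bmi_percentile(growth, sexi, cohort$age_days,
                       (cohort$fat_mass + cohort$fat_free_mass) /
                         (cohort$height_cm / 100)^2)

  drift28 <- function(intake) {
    fat <- cohort$fat_mass; ffm <- cohort$fat_free_mass
    h <- cohort$height_cm; ad <- cohort$age_days
    for (t in 1:28) {
      ee <- params$rmr_intercept[sexi] + params$rmr_slope * ffm +
        params$offday_activity +
        params$mvpa_net_cost * (fat + ffm) * em
      s <- intake - ee
      fat <- pmax(fat + params$fat_partition * s / params$energy_density_fat,
                  params$min_fat)
      ffm <- pmax(ffm + (1 - params$fat_partition) * s / params$energy_density_ffm,
                  params$min_ffm)
      h <- h + growth$velocity_cm[cbind(growth_idx(growth, ad), sexi)]
      ad <- ad + 1L
    }
    bmi_percentile(growth, sexi, pmin(ad, AGE_MAX_DAYS),
                   (fat + ffm) / (h / 100)^2) - p0
  }

  lo <- rep(500, nrow(cohort)); hi <- rep(6000, nrow(cohort))
  flo <- drift28(lo); fhi <- drift28(hi)
  bad <- flo > 0 | fhi < 0
  if (any(bad)) {
    stop("calibrate_intake: no maintenance intake in [500, 6000] kcal/day for agent(s) ",
         paste(utils::head(which(bad), 5), collapse = ", "), call. = FALSE)
  }
  mid <- (lo + hi) / 2
  for (it in 1:45) {
    fm <- drift28(mid)
    if (all(abs(fm) < tol)) break
    up <- fm < 0
    lo[up] <- mid[up]; hi[!up] <- mid[!up]
    mid <- (lo + hi) / 2
  }
  unname(mid)
}

#' Simulate one childhood arm (daily energy balance to age 18)
#'
#' Runs every agent day-by-day from its baseline age to exactly 18 years.
#' Intake follows the BMI-percentile-maintaining target trajectory computed at
#' the agent's *baseline* expected PA (so raising PA, with intake held at its
#' baseline-calibrated path, produces a caloric deficit and weight loss), plus
#' any scenario compensation adjustment.  Weekly active days are drawn
#' Binomial(7, mean/7) from uniforms keyed by `(seed, week)` -- identical
#' streams across paired arms (common random numbers), so a scenario with
#' `reduction_fraction = 0` and no compensation reproduces the baseline arm
#' bit for bit.
#'
#' @param cohort A `cohort` from [build_cohort()].
#' @param table The `strata_table` the cohort came from.
#' @param growth A `growth_reference`.
#' @param scenario A `scenario_spec`; the baseline arm is
#'   `scenario_spec(reduction_fraction = 0, offday_minutes = <same>, seed = <same>)`.
#' @param params A `metabolic_params`.
#' @return The cohort with columns `weight_18`, `bmi_18`, `weight_class_18`,
#'   `bmi_percentile_18`, `fat_mass_18`, `fat_free_mass_18`, `years_to_18`.
#' @export
simulate_childhood <- function(cohort, table, growth, scenario,
                               params = metabolic_params()) {
  stopifnot(inherits(scenario, "scenario_spec"))
  n <- nrow(cohort)
  sexi <- match(cohort$sex, SEX_LEVELS)
  offday <- scenario$offday_minutes

  m_base <- cohort$pa_days_mean
  m_scen <- apply_reduction(cohort, table, scenario)$pa_days_mean
  em <- expected_mvpa_minutes(m_base, offday)
  pb <- m_base / 7; ps <- m_scen / 7

  fat <- cohort$fat_mass; ffm <- cohort$fat_free_mass
  tfat <- fat; tffm <- ffm
  age0 <- cohort$age_days
  z0 <- stats::qnorm(cohort$bmi_percentile_at_baseline / 100)

  alpha <- params$fat_partition
  rf <- params$energy_density_fat; rl <- params$energy_density_ffm
  kmass <- params$mass_per_kcal
  rmr0 <- params$rmr_intercept[sexi]
  cost <- params$mvpa_net_cost
  base_act <- params$offday_activity

  idx0 <- growth_idx(growth, age0)
  h <- growth$height_cm[cbind(idx0, sexi)] +
    (cohort$height_cm - growth$height_cm[cbind(idx0, sexi)])
  hoff <- cohort$height_cm - growth$height_cm[cbind(idx0, sexi)]  # individual offset
  wstar_prev <- exp(growth$bmi_meanlog[cbind(idx0, sexi)] +
                      z0 * growth$bmi_sdlog[cbind(idx0, sexi)]) *
    ((growth$height_cm[cbind(idx0, sexi)] + hoff) / 100)^2

  total_days <- AGE_MAX_DAYS - min(age0)
  a_b <- a_s <- integer(n)
  n_clamped <- 0L

  for (t in seq_len(total_days)) {
    ad <- age0 + t
    act <- as.numeric(ad <= AGE_MAX_DAYS)
    i <- growth_idx(growth, ad)
    k <- cbind(i, sexi)
    hh <- growth$height_cm[k] + hoff

    d <- (t - 1L) %% 7L
    if (d == 0L) {
      u <- with_seed(derive_seed(scenario$seed, "week", (t - 1L) %/% 7L),
                     stats::runif(n))
      a_b <- stats::qbinom(u, 7L, pb)
      a_s <- stats::qbinom(u, 7L, ps)
    }
    min_b <- ifelse(d < a_b, 60, offday)
    min_s <- ifelse(d < a_s, 60, offday)

    # target (baseline-maintaining) trajectory and its intake
    bstar <- exp(growth$bmi_meanlog[k] + z0 * growth$bmi_sdlog[k])
    wstar <- bstar * (hh / 100)^2
    s_star <- (wstar - wstar_prev) / kmass
    wstar_prev <- wstar
    intake0 <- rmr0 + params$rmr_slope * tffm + base_act +
      cost * wstar * em + s_star
    tfat <- tfat + act * alpha * s_star / rf
    tffm <- tffm + act * (1 - alpha) * s_star / rl

    # realized arm
    w <- fat + ffm
    extra <- cost * w * pmax(min_s - min_b, 0)
    adjust <- intake_adjustment(extra, intake0, scenario)
    ee <- rmr0 + params$rmr_slope * ffm + base_act + cost * w * min_s
    surplus <- intake0 + adjust - ee
    fat <- fat + act * alpha * surplus / rf
    ffm <- ffm + act * (1 - alpha) * surplus / rl
    low <- fat < params$min_fat | ffm < params$min_ffm
    if (any(low)) {
      n_clamped <- n_clamped + sum(low)
      fat <- pmax(fat, params$min_fat)
      ffm <- pmax(ffm, params$min_ffm)
    }
  }
  if (n_clamped > 0L) {
    message("simulate_childhood: ", n_clamped, " agent-day updates clamped at the mass floor")
  }

  k18 <- cbind(growth_idx(growth, rep(AGE_MAX_DAYS, n)), sexi)
  h18 <- growth$height_cm[k18] + hoff
  w18 <- fat + ffm
  bmi18 <- w18 / (h18 / 100)^2
  out <- cohort
  out$fat_mass_18 <- fat
  out$fat_free_mass_18 <- ffm
  out$weight_18 <- w18
  out$bmi_18 <- bmi18
  out$bmi_percentile_18 <- bmi_percentile(growth, sexi, rep(AGE_MAX_DAYS, n), bmi18)
  out$weight_class_18 <- classify_weight(bmi18, cohort$sex, rep(AGE_MAX_DAYS, n), growth)
  out$years_to_18 <- (AGE_MAX_DAYS - age0) / DAYS_PER_YEAR
  out
}
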