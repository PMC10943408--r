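#' Scenario specification for disparity-reduction counterfactuals
#'
#' @param reduction_fraction Fraction `r` in [0, 1] of the PA disparity to
#'   close: every stratum's mean active days shifts by
#'   `r * (sex/age-band target - stratum mean)`, never downward.
#' @param offday_minutes Minutes of PA on days without a 60-minute bout
#'   (default 30; sensitivity range 0-60).
#' @param compensation_mode How caloric intake responds to the extra PA:
#'   `"none"`, `"fraction_of_extra"` (intake rises by
#'   `compensation_value` x extra PA expenditure, compensatory eating), or
#'   `"diet_improvement"` (total intake falls by 2\%).
#' @param compensation_value Fraction in [0, 1] for `"fraction_of_extra"`;
#'   for `"diet_improvement"` the total-intake multiplier change (default
#'   -0.02, i.e. a 2\% decrease).
#' @param seed Integer seed for scenario randomness.
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(reduction_fraction = 1, offday_minutes = 30,
                          compensation_mode = c("none", "fraction_of_extra",
                                                "diet_improvement"),
                          compensation_value = NULL, seed = 1L) {
  compensation_mode <- match.arg(compensation_mode)
  stopifnot(reduction_fraction >= 0, reduction_fraction <= 1,
            offday_minutes >= 0, offday_minutes <= 60)
  if (compensation_mode == "fraction_of_extra") {
    if (is.null(compensation_value)) compensation_value <- 0.5
    if (compensation_value < 0 || compensation_value > 1) {
      stop("compensation fraction must lie in [0, 1]", call. = FALSE)
    }
  } else if (compensation_mode == "diet_improvement") {
    if (is.null(compensation_value)) compensation_value <- -0.02
    stopifnot(compensation_value <= 0)
  } else {
    compensation_value <- 0
  }
  structure(list(reduction_fraction = reduction_fraction,
                 offday_minutes = offday_minutes,
                 compensation_mode = compensation_mode,
                 compensation_value = compensation_value,
                 seed = seed),
            class = "scenario_spec")
}

#' Target PA level for a sex and age band
#'
#' The scenario target is the highest mean PA-days/week observed across the
#' four FPL categories within the sex/age-band group (attained, in the packaged
#' table, by the >=400\% FPL stratum in every group).
#'
#' @param table A `strata_table`.
#' @param sex,age_band Group selectors.
#' @return Target mean active days/week.
#' @examples
#' target_level(load_table1(), "male", "6-10")  # 4.39
#' @export
target_level <- function(table, sex, age_band) {
  i <- which(table$sex == sex & table$age_band == age_band)
  if (!length(i)) stop("unknown sex/age_band group", call. = FALSE)
  max(table$pa_days_mean[i])
}

#' Apply the disparity-reduction shift to agent PA means
#'
#' Shifts each agent's individual mean active days upward by
#' `r * (target - stratum mean)` where the target is [target_level()] for the
#' agent's sex/age group.  The shift is applied to the individual mean
#' (preserving within-stratum dispersion) and is never negative; agents in the
#' stratum already at the target are unchanged.  Shifted means are capped at 7.
#'
#' @param cohort A `cohort` (or any data.frame with `sex`, `age_band`, `fpl`,
#'   `pa_days_mean`).
#' @param table The `strata_table` the cohort was built from.
#' @param spec A `scenario_spec`.
#' @return The cohort with `pa_days_mean` shifted.
#' @export
apply_reduction <- function(cohort, table, spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  key_tab <- paste(table$sex, table$age_band, table$fpl)
  key_coh <- paste(cohort$sex, cohort$age_band, cohort$fpl)
  m <- match(key_coh, key_tab)
  if (anyNA(m)) stop("cohort contains strata not present in the table", call. = FALSE)
  tgt <- vapply(seq_len(nrow(table)), function(i) {
    target_level(table, table$sex[i], table$age_band[i])
  }, numeric(1))
  shift <- pmax(spec$reduction_fraction * (tgt[m] - table$pa_days_mean[m]), 0)
  cohort$pa_days_mean <- pmin(cohort$pa_days_mean + shift, 7)
  cohort
}

#' Draw one week of active days for an agent
#'
#' Active days (days with a 60-minute PA bout) are drawn Binomial(7, mean/7),
#' a bounded integer draw whose expectation equals the agent's mean; remaining
#' days get `spec$offday_minutes` of PA.
#'
#' @param pa_days_mean Mean active days/week (vectorized).
#' @param spec A `scenario_spec`.
#' @param u Optional uniforms in (0,1) (one per agent) for common-random-number
#'   coupling; drawn from the session RNG when omitted.
#' @return List with integer `active_days` and `offday_minutes`.
#' @export
draw_week <- function(pa_days_mean, spec, u = NULL) {
  stopifnot(all(pa_days_mean >= 0), all(pa_days_mean <= 7))
  if (is.null(u)) u <- stats::runif(length(pa_days_mean))
  list(active_days = as.integer(stats::qbinom(u, 7L, pa_days_mean / 7)),
       offday_minutes = spec$offday_minutes)
}

#' Caloric-intake adjustment under a compensation setting
#'
#' `"none"` leaves intake unchanged; `"fraction_of_extra"` adds
#' `c x extra_pa_kcal` (compensatory eating); `"diet_improvement"` subtracts
#' 2\% of baseline intake (healthier diet accompanying more PA).
#'
#' @param extra_pa_kcal Extra PA expenditure vs baseline, kcal/day (>= 0).
#' @param baseline_intake Baseline calibrated intake, kcal/day.
#' @param spec A `scenario_spec`.
#' @return Intake adjustment in kcal/day (vectorized).
#' @export
intake_adjustment <- function(extra_pa_kcal, baseline_intake, spec) {
  stopifnot(all(extra_pa_kcal >= 0))
  switch(spec$compensation_mode,
    none = rep(0, length(extra_pa_kcal)),
    fraction_of_extra = spec$compensation_value * extra_pa_kcal,
    diet_improvement = spec$compensation_value * baseline_intake + 0 * extra_pa_kcal
  )
}
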