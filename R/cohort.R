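#' Cohort specification
#'
#' @param n_agents Number of simulated agents (>= 24, at least one per stratum
#'   in practice; allocation errors out if any stratum would be empty).
#' @param pa_day_sd_individual Individual-level dispersion (days/week) of mean
#'   PA days around the stratum mean.  The printed stratum SEs are survey
#'   standard errors of the mean, not person-level SDs, so this is a free
#'   model parameter; default 1.5 days/week.
#' @param seed Integer seed for all cohort randomness.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_agents = 50000L, pa_day_sd_individual = 1.5, seed = 1L) {
  stopifnot(n_agents >= 24, pa_day_sd_individual >= 0)
  structure(list(n_agents = as.integer(n_agents),
                 pa_day_sd_individual = pa_day_sd_individual,
                 seed = seed),
            class = "cohort_spec")
}

# Largest-remainder (Hamilton) apportionment of n among weights w;
# ties broken by position order (as printed in the strata table).
largest_remainder <- function(n, w) {
  q <- as.numeric(n) * as.numeric(w) / sum(as.numeric(w))
  base <- floor(q)
  left <- n - sum(base)
  if (left > 0) {
    ord <- order(-(q - base), seq_along(q))
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

# Truncated-normal sampler on [lo, hi] whose MEAN equals `mean` (the location
# parameter is solved by bisection so truncation does not bias the mean).
rtruncnorm_meanmatch <- function(n, mean, sd, lo = 0, hi = 7) {
  if (sd == 0 || n == 0) return(rep(mean, n))
  tmean <- function(mu) {
    a <- (lo - mu) / sd; b <- (hi - mu) / sd
    pa <- stats::pnorm(a); pb <- stats::pnorm(b)
    mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / (pb - pa)
  }
  f <- function(mu) tmean(mu) - mean
  mu <- stats::uniroot(f, lower = lo - 6 * sd, upper = hi + 6 * sd, tol = 1e-10)$root
  a <- (lo - mu) / sd; b <- (hi - mu) / sd
  u <- stats::runif(n, stats::pnorm(a), stats::pnorm(b))
  mu + sd * stats::qnorm(u)
}

#' Build the agent cohort from the strata table
#'
#' Allocates agents to the 24 strata proportionally to printed populations
#' (largest-remainder rounding), assigns each agent a uniform age-in-days
#' within its band, a baseline weight class drawn to match the printed
#' overweight/obesity prevalence in expectation, a BMI percentile consistent
#' with that class (uniform within the class band under the growth reference),
#' a height (reference median plus individual normal offset), body composition
#' (fat fraction by class and sex), and an individual mean PA-days/week drawn
#' from a mean-matched truncated normal on [0, 7].  The sampling weight of
#' every agent in a stratum is stratum population / stratum agent count, so
#' weights sum exactly to the printed national population.
#'
#' @param table A `strata_table` from [load_table1()].
#' @param growth A `growth_reference`.
#' @param spec A `cohort_spec`.
#' @return A `cohort` data.frame, one row per agent.
#' @examples
#' coh <- build_cohort(load_table1(), synthesize_growth_reference(1),
#'                     cohort_spec(n_agents = 2400, seed = 1))
#' sum(coh$sampling_weight) == sum(load_table1()$population)
#' @export
build_cohort <- function(table, growth, spec) {
  stopifnot(inherits(table, "strata_table"), inherits(growth, "growth_reference"),
            inherits(spec, "cohort_spec"))
  n_by_stratum <- largest_remainder(spec$n_agents, table$population)
  if (any(n_by_stratum == 0)) {
    empty <- paste(table$sex, table$age_band, table$fpl)[n_by_stratum == 0]
    stop("n_agents too small; empty strata: ", paste(empty, collapse = "; "),
         call. = FALSE)
  }

  # fat fraction at baseline by weight class, male/female
  fat_frac <- rbind(normal = c(0.20, 0.25), overweight = c(0.28, 0.32),
                    obese = c(0.35, 0.40))

  with_seed(derive_seed(spec$seed, "cohort"), {
    rows <- vector("list", nrow(table))
    for (i in seq_len(nrow(table))) {
      n <- n_by_stratum[i]
      sexi <- match(table$sex[i], SEX_LEVELS)
      band <- age_band_days(table$age_band[i])
      age <- sample(band[1]:band[2], n, replace = TRUE)

      pow <- table$overweight_prev[i] / 100
      pob <- table$obesity_prev[i] / 100
      u <- stats::runif(n)
      wc <- ifelse(u < pob, "obese", ifelse(u < pob + pow, "overweight", "normal"))
      # BMI percentile uniform within the class band; obesity capped at 99.8
      # to avoid the log-normal's extreme tail.
      pct <- stats::runif(n)
      pct <- ifelse(wc == "obese", 95 + pct * 4.8,
             ifelse(wc == "overweight", 85 + pct * 10, 2 + pct * 83))
      bmi <- bmi_at_percentile(growth, sexi, age, pct)

      hmed <- growth$height_cm[cbind(growth_idx(growth, age), sexi)]
      height <- hmed + stats::rnorm(n, 0, 5.5)
      weight <- bmi * (height / 100)^2
      ff <- fat_frac[wc, sexi]

      pa <- rtruncnorm_meanmatch(n, table$pa_days_mean[i],
                                 spec$pa_day_sd_individual)
      rows[[i]] <- data.frame(
        stratum = i, sex = table$sex[i], age_band = table$age_band[i],
        fpl = table$fpl[i], age_days = age, height_cm = height,
        fat_mass = ff * weight, fat_free_mass = (1 - ff) * weight,
        weight_kg = weight, bmi = bmi, bmi_percentile_at_baseline = pct,
        pa_days_mean = pa, weight_class = wc,
        sampling_weight = table$population[i] / n,
        stringsAsFactors = FALSE
      )
    }
    coh <- do.call(rbind, rows)
    coh$id <- seq_len(nrow(coh))
    coh <- coh[, c("id", setdiff(names(coh), "id"))]
    class(coh) <- c("cohort", "data.frame")
    coh
  })
}

#' Classify an agent's weight status against the growth reference
#'
#' Normal weight below the 85th BMI percentile threshold, overweight in
#' [85th, 95th), obesity at or above the 95th.  Boundaries are half-open and
#' classify upward (a BMI exactly at a threshold takes the heavier class).
#'
#' @param bmi BMI value(s), kg/m^2.
#' @param sex `"male"`/`"female"` (recycled).
#' @param age_days Age(s) in days; must lie in the 6-18 y reference range.
#' @param growth A `growth_reference`.
#' @return Character vector in `c("normal", "overweight", "obese")`.
#' @export
classify_weight <- function(bmi, sex, age_days, growth) {
  if (any(age_days < AGE_MIN_DAYS | age_days > AGE_MAX_DAYS)) {
    stop("age outside the 6-18 y growth reference range", call. = FALSE)
  }
  sexi <- match(sex, SEX_LEVELS)
  if (anyNA(sexi)) stop("sex must be 'male' or 'female'", call. = FALSE)
  k <- cbind(growth_idx(growth, age_days), sexi)
  unname(ifelse(bmi >= growth$bmi_p95[k], "obese",
                ifelse(bmi >= growth$bmi_p85[k], "overweight", "normal")))
}
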