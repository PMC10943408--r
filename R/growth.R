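#' Synthesize a growth reference (heights and BMI percentile curves)
#'
#' Builds a seeded synthetic stand-in for nationally representative growth
#' charts: per sex and age-in-days from 6 to 18 years, a median height curve
#' (logistic pubertal spurt on a linear trend), its daily velocity, and a
#' log-normal BMI distribution (location/scale by age) from which BMI
#' percentiles and the 85th/95th-percentile overweight/obesity thresholds are
#' derived.  The object is a stand-in, NOT fitted to real CDC LMS tables, but
#' is swappable for them: anything exposing the same fields works downstream.
#'
#' @param seed Integer seed; the same seed always yields the identical table.
#' @return A `growth_reference` list with `age_days` and, per quantity,
#'   matrices `[age, sex]` (`height_cm`, `velocity_cm`, `bmi_meanlog`,
#'   `bmi_sdlog`, `bmi_p85`, `bmi_p95`); column 1 = male, 2 = female.
#' @examples
#' gr <- synthesize_growth_reference(1)
#' range(gr$height_cm[, "male"])
#' @export
synthesize_growth_reference <- function(seed = 1L) {
  age_days <- AGE_MIN_DAYS:AGE_MAX_DAYS
  age_yr <- age_days / DAYS_PER_YEAR

  # +/-0.5% seeded jitter on curve parameters: seeds matter, shapes preserved.
  jit <- with_seed(derive_seed(seed, "growth"), stats::rnorm(12, 1, 0.005))
  logis_cdf <- function(a, t0, s) 1 / (1 + exp(-(a - t0) / s))

  height_curve <- function(h6, h18, t0, s, slope) {
    gain_lin <- slope * (age_yr - 6)
    l0 <- logis_cdf(6, t0, s)
    amp <- (h18 - h6 - slope * 12) / (logis_cdf(18, t0, s) - l0)
    h6 + gain_lin + amp * (logis_cdf(age_yr, t0, s) - l0)
  }
  h_m <- height_curve(116.0 * jit[1], 176.0 * jit[2], 13.5 * jit[3], 1.0, 3.0)
  h_f <- height_curve(115.5 * jit[4], 163.0 * jit[5], 11.5 * jit[6], 1.0, 3.0)

  # Median BMI rises from ~15.4 to ~21.5 (male) / 21.2 (female); dispersion of
  # log-BMI widens with age (right-skew grows through adolescence).
  bmi_median <- function(m6, m18, pow) m6 + (m18 - m6) * ((age_yr - 6) / 12)^pow
  mu_m <- log(bmi_median(15.4 * jit[7], 21.5 * jit[8], 1.15))
  mu_f <- log(bmi_median(15.3 * jit[9], 21.2 * jit[10], 1.10))
  sig <- (0.10 + 0.10 * (age_yr - 6) / 12)
  sig_m <- sig * jit[11]
  sig_f <- sig * jit[12]

  z85 <- stats::qnorm(0.85)
  z95 <- stats::qnorm(0.95)
  two <- function(m, f) {
    out <- cbind(male = m, female = f)
    rownames(out) <- NULL
    out
  }
  gr <- list(
    age_days = age_days,
    height_cm = two(h_m, h_f),
    velocity_cm = two(c(diff(h_m), 0), c(diff(h_f), 0)),
    bmi_meanlog = two(mu_m, mu_f),
    bmi_sdlog = two(sig_m, sig_f),
    bmi_p85 = two(exp(mu_m + z85 * sig_m), exp(mu_f + z85 * sig_f)),
    bmi_p95 = two(exp(mu_m + z95 * sig_m), exp(mu_f + z95 * sig_f)),
    seed = seed
  )
  stopifnot(all(diff(gr$height_cm[, 1]) >= 0), all(diff(gr$height_cm[, 2]) >= 0),
            all(gr$bmi_p85 < gr$bmi_p95))
  class(gr) <- "growth_reference"
  gr
}

# Clamped row index into growth tables for a vector of ages in days.
growth_idx <- function(growth, age_days) {
  pmin(pmax(as.integer(round(age_days)) - AGE_MIN_DAYS + 1L,
            1L), length(growth$age_days))
}

# BMI value at a given percentile (0-100), vectorized over agents.
bmi_at_percentile <- function(growth, sex_idx, age_days, percentile) {
  i <- growth_idx(growth, age_days)
  k <- cbind(i, sex_idx)
  exp(growth$bmi_meanlog[k] + stats::qnorm(percentile / 100) * growth$bmi_sdlog[k])
}

# Percentile (0-100) of a BMI value, vectorized.
bmi_percentile <- function(growth, sex_idx, age_days, bmi) {
  i <- growth_idx(growth, age_days)
  k <- cbind(i, sex_idx)
  100 * stats::pnorm((log(bmi) - growth$bmi_meanlog[k]) / growth$bmi_sdlog[k])
}
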