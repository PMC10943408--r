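# Shared fixtures, built once per test run (kept small for the 1-CPU budget).

.fix <- new.env(parent = emptyenv())

fix_table <- function() {
  if (is.null(.fix$tab)) .fix$tab <- load_table1()
  .fix$tab
}

fix_growth <- function() {
  if (is.null(.fix$growth)) .fix$growth <- synthesize_growth_reference(42)
  .fix$growth
}

fix_markov <- function() {
  if (is.null(.fix$markov)) .fix$markov <- synthesize_markov_params(42)
  .fix$markov
}

fix_cohort <- function(n = 2400, seed = 7) {
  key <- paste0("coh_", n, "_", seed)
  if (is.null(.fix[[key]])) {
    .fix[[key]] <- build_cohort(fix_table(), fix_growth(),
                                cohort_spec(n, seed = seed))
  }
  .fix[[key]]
}

# Rolling maintenance-intake simulation: recalibrate every 28 days (the
# model's intake policy) and integrate the energy balance daily.  With
# `frozen_intakes` (a blocks x agents matrix from a previous run) the intake
# schedule is replayed instead of recalibrated, so extra PA creates a deficit.
roll_sim <- function(coh, gr, p, days, extra_min = 0, tol = 0.005,
                     frozen_intakes = NULL) {
  cur <- coh
  sxi <- match(cur$sex, c("male", "female"))
  n_blocks <- ceiling(days / 28)
  intakes <- matrix(NA_real_, n_blocks, nrow(coh))
  day <- 0
  for (b in seq_len(n_blocks)) {
    intake <- if (is.null(frozen_intakes)) {
      calibrate_intake(cur, gr, p, tol = tol)
    } else {
      frozen_intakes[b, ]
    }
    intakes[b, ] <- intake
    em <- (cur$pa_days_mean * 60 + (7 - cur$pa_days_mean) * 30) / 7 + extra_min
    for (t in seq_len(min(28, days - day))) {
      act <- as.numeric(cur$age_days < 6574L)
      ee <- p$rmr_intercept[sxi] + p$rmr_slope * cur$fat_free_mass +
        p$offday_activity +
        p$mvpa_net_cost * (cur$fat_mass + cur$fat_free_mass) * em
      s <- intake - ee
      cur$fat_mass <- cur$fat_mass + act * p$fat_partition * s / p$energy_density_fat
      cur$fat_free_mass <- cur$fat_free_mass +
        act * (1 - p$fat_partition) * s / p$energy_density_ffm
      cur$height_cm <- cur$height_cm +
        act * gr$velocity_cm[cbind(paequity:::growth_idx(gr, cur$age_days), sxi)]
      cur$age_days <- pmin(cur$age_days + 1L, 6574L)
    }
    day <- day + 28
  }
  w <- cur$fat_mass + cur$fat_free_mass
  bmi <- w / (cur$height_cm / 100)^2
  list(weight = w, bmi = bmi, age = cur$age_days,
       pct = paequity:::bmi_percentile(gr, sxi, cur$age_days, bmi),
       intakes = intakes)
}

# A degenerate Markov parameter set: identity transitions among living states,
# no events, no background mortality. Useful for absorbing/identity tests.
degenerate_markov <- function(base = fix_markov()) {
  mp <- base
  mp$P[] <- 0
  for (s in seq_len(mp$n_states)) mp$P[s, s, , ] <- 1
  mp$event_prob[] <- 0
  mp
}
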