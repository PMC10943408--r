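# Synthetic stand-in for the adult multi-state disease model parameters
# (the real values live in an unpublished supplement; these are seeded,
# order-of-magnitude-plausible tables that satisfy every structural invariant
# the downstream model needs, and are labelled non-authoritative).

# 15 mutually exclusive states: 3 BMI categories x 4 risk-severity tiers
# (metabolically healthy, moderate risk, high risk, diseased), two shared
# post-event states, and death.  This topology is a declared stand-in: the
# source model states only the count (15) and the BMI-category entry rule.
markov_state_labels <- function() {
  c(paste(rep(c("normal", "overweight", "obese"), each = 4),
          rep(c("healthy", "moderate", "high", "diseased"), 3), sep = "_"),
    "post_cvd", "post_complex", "death")
}

#' Synthesize the adult Markov disease-model parameter set
#'
#' Generates a seeded synthetic stand-in for the supplement-only parameter
#' tables of the 15-state adult model: annual transition probabilities by
#' (state, age 18-100, sex); annual probabilities of CHD events, strokes,
#' type 2 diabetes onset and cancer onset by (state, age, sex); event case
#' fatality by age; annual direct medical cost per state and one-time cost per
#' event (2023 USD); utility weights; and a daily wage.  Event risks carry an
#' enforced BMI gradient (normal <= overweight <= obese at fixed tier, age and
#' sex); transition rows sum to one and death is absorbing, by construction.
#'
#' @param seed Integer seed; identical seeds give byte-identical sets.
#' @return A `markov_param_set` list; see fields in the source. All magnitudes
#'   are plausible stand-ins, not estimates.
#' @examples
#' mp <- synthesize_markov_params(7)
#' rowSums(mp$P[, , 1, 1])  # each 1
#' @export
synthesize_markov_params <- function(seed = 1L) {
  states <- markov_state_labels()
  ns <- length(states)
  death <- ns
  ages <- 18:100
  na <- length(ages)
  bmi_of_state <- c(rep(1:3, each = 4), NA, NA, NA)  # 1=N 2=OW 3=OB
  tier_of_state <- c(rep(1:4, 3), 5L, 6L, NA)

  jr <- with_seed(derive_seed(seed, "markov"), stats::rnorm(40, 1, 0.03))
  jr <- pmax(pmin(jr, 1.15), 0.85)
  j <- function(i) jr[i]

  rel_age <- outer(ages - 18, c(male = 1, female = 1))  # [age, sex]

  # Background annual mortality: Gompertz in age, lower for females.
  mort <- pmin(cbind(male = 6e-4 * j(1) * exp(0.075 * (ages - 18)),
                     female = 4e-4 * j(2) * exp(0.075 * (ages - 18))), 0.95)
  mort_mult <- c(1.0, 1.1, 1.3, 1.8)[pmin(tier_of_state, 4)]
  mort_mult[13:14] <- c(2.0, 2.6)
  mort_bmi <- c(1.0, 1.05, 1.15)

  # Tier progression/regression within a BMI category.
  base_prog <- pmin(0.02 * j(3) + 0.0015 * (ages - 18), 0.15)    # by age
  prog_bmi <- c(1.0, 1.3, 1.6) * j(4)
  p_regress <- 0.01 * j(5)
  p_dis_to_postcvd <- 0.03 * j(6)
  p_dis_to_postcx <- 0.01 * j(7)
  p_postcvd_to_cx <- 0.02 * j(8)

  P <- array(0, dim = c(ns, ns, na, 2),
             dimnames = list(states, states, ages, SEX_LEVELS))
  for (sx in 1:2) {
    for (ai in seq_len(na)) {
      M <- matrix(0, ns, ns)
      for (s in 1:(ns - 1L)) {
        d <- min(mort[ai, sx] * mort_mult[s] *
                   (if (!is.na(bmi_of_state[s])) mort_bmi[bmi_of_state[s]] else 1), 0.95)
        row <- numeric(ns)
        row[death] <- d
        if (s <= 12L) {
          b <- bmi_of_state[s]; tr <- tier_of_state[s]
          if (tr < 4L) row[s + 1L] <- base_prog[ai] * prog_bmi[b]
          if (tr > 1L) row[s - 1L] <- p_regress
          if (tr == 4L) {
            row[13L] <- p_dis_to_postcvd * prog_bmi[b]
            row[14L] <- p_dis_to_postcx * prog_bmi[b]
          }
        } else if (s == 13L) {
          row[14L] <- p_postcvd_to_cx
        }
        tot <- sum(row)
        if (tot > 0.98) row <- row * (0.98 / tot)
        row[s] <- 1 - sum(row)
        M[s, ] <- row
      }
      M[death, death] <- 1
      P[, , ai, sx] <- M
    }
  }

  # Annual event probabilities by (type, state, age, sex).
  base_ev <- list(
    chd    = pmin(cbind(2.0e-4 * exp(0.070 * (ages - 18)),
                        1.2e-4 * exp(0.070 * (ages - 18))) * j(9), 0.08),
    stroke = pmin(cbind(1.0e-4 * exp(0.075 * (ages - 18)),
                        0.8e-4 * exp(0.075 * (ages - 18))) * j(10), 0.06),
    t2d    = pmin(cbind(1.0e-3 * (1 + 0.03 * (ages - 18)),
                        0.9e-3 * (1 + 0.03 * (ages - 18))) * j(11), 0.03),
    cancer = pmin(cbind(1.5e-4 * exp(0.080 * (ages - 18)),
                        1.5e-4 * exp(0.080 * (ages - 18))) * j(12), 0.08)
  )
  tier_ev <- c(1.0, 1.5, 2.2, 3.0, 3.5, 4.0)  # tiers 1-4, post_cvd, post_complex
  bmi_ev <- rbind(chd = c(1, 1.35, 1.9), stroke = c(1, 1.30, 1.8),
                  t2d = c(1, 1.80, 3.2), cancer = c(1, 1.20, 1.5))
  event_prob <- array(0, dim = c(4, ns, na, 2),
                      dimnames = list(EVENT_TYPES, states, ages, SEX_LEVELS))
  for (k in 1:4) {
    for (s in 1:(ns - 1L)) {
      mult <- tier_ev[tier_of_state[s]] *
        (if (!is.na(bmi_of_state[s])) bmi_ev[k, bmi_of_state[s]] else 1)
      for (sx in 1:2) {
        event_prob[k, s, , sx] <- pmin(base_ev[[k]][, sx] * mult, 0.25)
      }
    }
  }

  event_fatality <- rbind(
    chd    = pmin(0.12 * j(13) * (1 + 0.012 * (ages - 18)), 0.5),
    stroke = pmin(0.18 * j(14) * (1 + 0.012 * (ages - 18)), 0.6),
    t2d    = pmin(0.02 * j(15) * (1 + 0.010 * (ages - 18)), 0.1),
    cancer = pmin(0.30 * j(16) * (1 + 0.008 * (ages - 18)), 0.7)
  )
  colnames(event_fatality) <- ages

  # Annual direct medical cost per state (2023 USD), mild age growth.
  tier_cost <- c(400, 1800, 4500, 11000, 9000, 16000) * j(17)
  bmi_cost <- c(1.0, 1.15, 1.4)
  age_cost <- pmin(1 + 0.01 * (ages - 18), 2)
  state_cost <- array(0, dim = c(ns, na, 2),
                      dimnames = list(states, ages, SEX_LEVELS))
  for (s in 1:(ns - 1L)) {
    base <- tier_cost[tier_of_state[s]] *
      (if (!is.na(bmi_of_state[s])) bmi_cost[bmi_of_state[s]] else 1)
    state_cost[s, , 1] <- base * age_cost
    state_cost[s, , 2] <- base * age_cost
  }

  event_cost <- c(chd = 25000, stroke = 32000, t2d = 9000, cancer = 45000) * j(18)

  # Utility weights (age-flat stand-ins); chosen so that the worst state
  # utility minus all four event disutilities stays above zero -- the QALY
  # floor never binds, keeping expectation and simulation laws identical.
  tier_util <- c(0.93, 0.87, 0.80, 0.68, 0.62, 0.55)
  bmi_util <- c(1.0, 0.98, 0.95)
  utility <- vapply(1:(ns - 1L), function(s) {
    max(tier_util[tier_of_state[s]] *
          (if (!is.na(bmi_of_state[s])) bmi_util[bmi_of_state[s]] else 1), 0.5)
  }, numeric(1))
  utility <- c(utility, 0)
  names(utility) <- states
  event_disutility <- c(chd = 0.06, stroke = 0.08, t2d = 0.03, cancer = 0.08)

  mp <- list(
    states = states, n_states = ns, death_state = death,
    entry_states = c(normal = 1L, overweight = 5L, obese = 9L),
    bmi_of_state = bmi_of_state, tier_of_state = tier_of_state,
    ages = ages, P = P,
    event_prob = event_prob, event_fatality = event_fatality,
    state_cost = state_cost, event_cost = event_cost,
    utility = utility, event_disutility = event_disutility,
    daily_wage = 180 * j(19),  # 2023 USD stand-in
    seed = seed
  )
  class(mp) <- "markov_param_set"
  validate_markov_params(mp)
  mp
}

#' Validate a Markov parameter set against its structural invariants
#'
#' Checks: every transition row sums to 1 within 1e-12; death is absorbing;
#' all probabilities lie in [0,1]; event probabilities are non-decreasing in
#' BMI category at fixed tier, age and sex; utilities lie in [0,1]; costs are
#' non-negative.
#'
#' @param mp A `markov_param_set`.
#' @return `mp`, invisibly; errors describe the first violated invariant.
#' @export
validate_markov_params <- function(mp) {
  rs <- apply(mp$P, c(1, 3, 4), sum)
  if (any(abs(rs - 1) > 1e-12)) {
    bad <- which(abs(rs - 1) > 1e-12, arr.ind = TRUE)[1, ]
    stop(sprintf("transition row does not sum to 1: state=%s age=%s sex=%s",
                 mp$states[bad[1]], mp$ages[bad[2]], SEX_LEVELS[bad[3]]), call. = FALSE)
  }
  dth <- mp$death_state
  if (any(mp$P[dth, dth, , ] != 1)) stop("death state is not absorbing", call. = FALSE)
  stop_if_not_prob(mp$P, "transition probabilities")
  stop_if_not_prob(mp$event_prob, "event probabilities")
  stop_if_not_prob(mp$event_fatality, "event fatality")
  stop_if_not_prob(mp$utility, "utilities")
  if (any(mp$state_cost < 0) || any(mp$event_cost < 0)) {
    stop("costs must be non-negative", call. = FALSE)
  }
  # BMI gradient: at fixed tier, N <= OW <= OB for every event/age/sex.
  for (tier in 1:4) {
    sN <- tier; sOW <- 4L + tier; sOB <- 8L + tier
    if (any(mp$event_prob[, sOW, , ] < mp$event_prob[, sN, , ]) ||
        any(mp$event_prob[, sOB, , ] < mp$event_prob[, sOW, , ])) {
      stop("event probabilities violate the BMI gradient at tier ", tier, call. = FALSE)
    }
  }
  invisible(mp)
}
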