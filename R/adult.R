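#' Markov entry state from weight class at age 18
#'
#' Agents enter the adult model at the metabolically healthy state of their
#' BMI category at the end of childhood.  Weight change during childhood that
#' does not change the BMI category does not change the entry state (the
#' conservative rule: outcome probabilities depend on category only).
#'
#' @param weight_class `"normal"`, `"overweight"`, or `"obese"` (vectorized).
#' @param params A `markov_param_set`.
#' @return Integer state index (1-based into `params$states`).
#' @export
entry_state <- function(weight_class, params) {
  idx <- params$entry_states[match(weight_class,
                                   c("normal", "overweight", "obese"))]
  if (anyNA(idx)) stop("invalid weight class", call. = FALSE)
  unname(idx)
}

#' Start a life-course record
#'
#' @param entry Integer entry state (from [entry_state()]).
#' @param sex `"male"` or `"female"`.
#' @return A `lifecourse_record`.
#' @export
lifecourse_record <- function(entry, sex) {
  structure(list(
    sex = sex, age = 18L, state = as.integer(entry), alive = TRUE,
    path = list(age = integer(), state = integer(),
                events = matrix(0L, 0, 4, dimnames = list(NULL, EVENT_TYPES))),
    life_years = 0L,
    events_total = stats::setNames(integer(4), EVENT_TYPES),
    deaths_cause = stats::setNames(integer(4), EVENT_TYPES),
    censored = FALSE
  ), class = "lifecourse_record")
}

# Annual-cycle law (shared by simulation and the expectation oracle):
# 1. transition sampled from the (state, age, sex) row (death prob in the row
#    is background mortality); 2. if alive, each event type drawn from the
#    post-transition state; a fatal event (case-fatality draw, evaluated in
#    fixed type order) kills at year end with attributed cause; 3. the year's
#    accruals belong to agents alive after the transition.

#' Advance a life-course record by one year
#'
#' Samples one state transition, then event and case-fatality draws from the
#' post-transition state.  Death is absorbing: a dead record is returned
#' unchanged.  Uses the session RNG (`set.seed()` for determinism).
#'
#' @param record A `lifecourse_record`.
#' @param params A `markov_param_set`.
#' @param count_recurrent Count repeat events of a type already experienced?
#'   Default `FALSE` (first onset per type per agent).
#' @return The updated record.
#' @export
step_year <- function(record, params, count_recurrent = FALSE) {
  if (!record$alive) return(record)
  ai <- record$age - 17L
  if (ai > length(params$ages)) stop("age beyond parameter range", call. = FALSE)
  sx <- match(record$sex, SEX_LEVELS)
  row <- params$P[record$state, , ai, sx]
  if (abs(sum(row) - 1) > 1e-9) {
    stop(sprintf("malformed transition row (sum != 1): state=%s age=%d sex=%s",
                 params$states[record$state], record$age, record$sex), call. = FALSE)
  }
  new_state <- findInterval(stats::runif(1), cumsum(row),
                            left.open = TRUE) + 1L
  ev <- integer(4)
  if (new_state != params$death_state) {
    fatal_cause <- 0L
    for (k in 1:4) {
      if (stats::runif(1) < params$event_prob[k, new_state, ai, sx]) {
        if (count_recurrent || record$events_total[k] == 0L) ev[k] <- 1L
        if (fatal_cause == 0L &&
            stats::runif(1) < params$event_fatality[k, ai]) {
          fatal_cause <- k
        }
      }
    }
    record$life_years <- record$life_years + 1L
    record$path$age <- c(record$path$age, record$age)
    record$path$state <- c(record$path$state, new_state)
    record$path$events <- rbind(record$path$events, ev)
    record$events_total <- record$events_total + ev
    record$state <- new_state
    if (fatal_cause > 0L) {
      record$alive <- FALSE
      record$state <- params$death_state
      record$deaths_cause[fatal_cause] <- 1L
    }
  } else {
    record$alive <- FALSE
    record$state <- params$death_state
  }
  record$age <- record$age + 1L
  record
}

#' Run a full adult life course
#'
#' Iterates [step_year()] from age 18 until death or `max_age` (survivors at
#' the cap are censored and flagged).
#'
#' @param entry Integer entry state.
#' @param sex `"male"` or `"female"`.
#' @param params A `markov_param_set`.
#' @param seed Optional seed for a reproducible record.
#' @param max_age Censoring age (default 100).
#' @param count_recurrent See [step_year()].
#' @return A completed `lifecourse_record`.
#' @export
run_lifecourse <- function(entry, sex, params, seed = NULL, max_age = 100,
                           count_recurrent = FALSE) {
  run1 <- function() {
    rec <- lifecourse_record(entry, sex)
    while (rec$alive && rec$age <= max_age) {
      rec <- step_year(rec, params, count_recurrent)
    }
    if (rec$alive) rec$censored <- TRUE
    rec
  }
  if (is.null(seed)) run1() else with_seed(seed, run1())
}

#' Analytic state-occupancy distribution (matrix-product oracle)
#'
#' Exact per-year occupancy probabilities over all 15 states for a given entry
#' state and sex, under the same annual law as the simulation (transition,
#' then event case fatality).  Row `i` is the distribution at the end of the
#' year in which the agent is aged `17 + i`.
#'
#' @param entry Integer entry state.
#' @param sex `"male"` or `"female"`.
#' @param params A `markov_param_set`.
#' @param n_years Number of annual cycles (default to age 100).
#' @return Matrix `[n_years, 15]` of probabilities (rows sum to 1).
#' @export
markov_occupancy <- function(entry, sex, params, n_years = 83) {
  sx <- match(sex, SEX_LEVELS)
  ns <- params$n_states
  dth <- params$death_state
  occ <- numeric(ns - 1L); occ[entry] <- 1
  pdead <- 0
  out <- matrix(0, n_years, ns, dimnames = list(NULL, params$states))
  for (ai in seq_len(n_years)) {
    P <- params$P[, , min(ai, length(params$ages)), sx]
    occ2 <- as.numeric(occ %*% P[1:(ns - 1L), 1:(ns - 1L)])
    pdead <- pdead + sum(occ * P[1:(ns - 1L), dth])
    # event case fatality from the post-transition state
    ev <- params$event_prob[, 1:(ns - 1L), min(ai, length(params$ages)), sx]
    f <- params$event_fatality[, min(ai, length(params$ages))]
    esurv <- apply(1 - ev * f, 2, prod)
    pdead <- pdead + sum(occ2 * (1 - esurv))
    occ <- occ2 * esurv
    out[ai, 1:(ns - 1L)] <- occ
    out[ai, dth] <- pdead
  }
  out
}

# Expected discounted adult outcomes per (entry BMI category, sex), valued at
# age 18 (the caller rescales by each agent's years from the 2023 reference).
# Exact conditional expectations under the annual law above -- used as the
# default adult engine in run_pair (Rao-Blackwellised over adult randomness).
expected_adult_outcomes <- function(params, econ, max_age = 100,
                                    count_recurrent = FALSE) {
  ns <- params$n_states; nl <- ns - 1L
  na_yr <- max_age - 18L + 1L
  metrics <- c("qaly", "life_years", "direct_usd", "productivity_usd",
               paste0("events_", EVENT_TYPES), paste0("deaths_", EVENT_TYPES),
               "deaths_total")
  out <- array(0, dim = c(3, 2, length(metrics)),
               dimnames = list(c("normal", "overweight", "obese"), SEX_LEVELS,
                               metrics))
  wage <- econ$daily_wage %||% params$daily_wage
  r <- econ$discount_rate
  for (sx in 1:2) {
    for (e in 1:3) {
      occ <- numeric(nl); occ[params$entry_states[e]] <- 1
      # occ_noev[k, s]: P(alive, in state s, no type-k event yet) -- needed
      # for first-onset-per-type event counts (the default counting rule)
      occ_noev <- matrix(0, 4, nl); occ_noev[, params$entry_states[e]] <- 1
      acc <- stats::setNames(numeric(length(metrics)), metrics)
      for (ai in seq_len(na_yr)) {
        aidx <- min(ai, length(params$ages))
        P <- params$P[, , aidx, sx]
        occ2 <- as.numeric(occ %*% P[1:nl, 1:nl])
        d_trans <- sum(occ * P[1:nl, ns])
        ev <- params$event_prob[, 1:nl, aidx, sx]      # 4 x nl
        f <- params$event_fatality[, aidx]
        evf <- ev * f
        esurv <- apply(1 - evf, 2, prod)
        # P(die of type k) = e_k f_k * prod_{j<k} (1 - e_j f_j)
        pdie <- evf
        for (k in 2:4) pdie[k, ] <- pdie[k, ] * apply(1 - evf[1:(k - 1), , drop = FALSE], 2, prod)

        df <- (1 + r)^(-(ai - 1))
        util_year <- pmax(params$utility[1:nl] -
                            colSums(ev * params$event_disutility), 0)
        acc["qaly"] <- acc["qaly"] + df * sum(occ2 * util_year)
        acc["life_years"] <- acc["life_years"] + sum(occ2)
        acc["direct_usd"] <- acc["direct_usd"] + df *
          sum(occ2 * (params$state_cost[1:nl, aidx, sx] +
                        colSums(ev * params$event_cost)))
        acc["productivity_usd"] <- acc["productivity_usd"] + df *
          sum(occ2 * (wage * (1 - util_year) * DAYS_PER_YEAR))
        occ_noev2 <- occ_noev %*% P[1:nl, 1:nl]
        for (k in 1:4) {
          n_events <- if (count_recurrent) sum(occ2 * ev[k, ]) else
            sum(occ_noev2[k, ] * ev[k, ])
          acc[paste0("events_", EVENT_TYPES[k])] <-
            acc[paste0("events_", EVENT_TYPES[k])] + n_events
          acc[paste0("deaths_", EVENT_TYPES[k])] <-
            acc[paste0("deaths_", EVENT_TYPES[k])] + sum(occ2 * pdie[k, ])
          # still no k event: survive other types' fatality, avoid k entirely
          other <- apply(1 - evf[-k, , drop = FALSE], 2, prod)
          occ_noev[k, ] <- occ_noev2[k, ] * (1 - ev[k, ]) * other
        }
        acc["deaths_total"] <- acc["deaths_total"] + d_trans +
          sum(occ2 * (1 - esurv))
        occ <- occ2 * esurv
      }
      # survivors at the age cap are censored, not counted as deaths
      out[e, sx, ] <- acc
    }
  }
  out
}

# Vectorized sampled adult cohort with common-random-number streams keyed by
# (seed, year, purpose); same entry states + same seed => identical paths.
simulate_adult_cohort <- function(entry, sexi, params, econ, seed,
                                  max_age = 100, count_recurrent = FALSE) {
  n <- length(entry)
  ns <- params$n_states
  state <- as.integer(entry)
  wage <- econ$daily_wage %||% params$daily_wage
  r <- econ$discount_rate
  qaly <- direct <- prod_loss <- numeric(n)
  ly <- numeric(n)
  events <- matrix(0, n, 4, dimnames = list(NULL, EVENT_TYPES))
  had <- matrix(FALSE, n, 4)
  deaths_cause <- matrix(0, n, 4, dimnames = list(NULL, EVENT_TYPES))
  occupancy <- matrix(0, max_age - 17L, ns)

  for (age in 18:max_age) {
    ai <- min(age - 17L, length(params$ages))
    alive <- state != params$death_state
    if (!any(alive)) {
      occupancy[(age - 17L):(max_age - 17L), ns] <-
        occupancy[(age - 17L):(max_age - 17L), ns] + n
      break
    }
    u <- with_seed(derive_seed(seed, "adult-trans", age), stats::runif(n))
    new_state <- state
    for (sx in 1:2) {
      for (s in unique(state[alive & sexi == sx])) {
        m <- alive & sexi == sx & state == s
        cum <- cumsum(params$P[s, , ai, sx])
        new_state[m] <- findInterval(u[m], cum, left.open = TRUE) + 1L
      }
    }
    survived <- alive & new_state != params$death_state
    ly <- ly + survived
    df <- (1 + r)^(-(age - 18))
    fatal <- integer(n)
    ev_dis <- numeric(n)
    for (k in 1:4) {
      ue <- with_seed(derive_seed(seed, "adult-event", EVENT_TYPES[k], age),
                      stats::runif(n))
      pk <- numeric(n)
      pk[survived] <- params$event_prob[cbind(k, new_state[survived], ai, sexi[survived])]
      evk <- survived & ue < pk
      count_k <- evk & (count_recurrent | !had[, k])
      events[, k] <- events[, k] + count_k
      had[, k] <- had[, k] | evk
      direct <- direct + df * params$event_cost[k] * evk
      ev_dis <- ev_dis + params$event_disutility[k] * evk
      uf <- with_seed(derive_seed(seed, "adult-fatal", EVENT_TYPES[k], age),
                      stats::runif(n))
      newly_fatal <- evk & fatal == 0L & uf < params$event_fatality[k, ai]
      fatal[newly_fatal] <- k
    }
    util_year <- numeric(n)
    util_year[survived] <- pmax(params$utility[new_state[survived]] -
                                  ev_dis[survived], 0)
    qaly <- qaly + df * util_year * survived
    direct <- direct + df * ifelse(survived,
                                   params$state_cost[cbind(new_state, ai, sexi)], 0)
    prod_loss <- prod_loss + df * wage * (1 - util_year) * DAYS_PER_YEAR * survived
    for (k in 1:4) deaths_cause[fatal == k, k] <- deaths_cause[fatal == k, k] + 1
    new_state[fatal > 0L] <- params$death_state
    state <- new_state
    occupancy[age - 17L, ] <- tabulate(state, ns)
  }
  list(qaly = qaly, life_years = ly, direct_usd = direct,
       productivity_usd = prod_loss, events = events,
       deaths_cause = deaths_cause,
       dead = state == params$death_state,
       occupancy = occupancy)
}
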