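#' Economic evaluation parameters
#'
#' @param discount_rate Annual discount rate (default 0.03) applied to all
#'   past and future costs and QALYs.
#' @param reference_year Costs are expressed in this year's US dollars and
#'   discounted to it (default 2023, the cohort start).
#' @param daily_wage Daily wage (2023 USD) for the presenteeism proxy; `NULL`
#'   uses the wage in the Markov parameter set.
#' @param perspective `"societal"` (direct + productivity) or `"payer"`
#'   (direct only).
#' @return An `econ_params` list.
#' @export
econ_params <- function(discount_rate = 0.03, reference_year = 2023,
                        daily_wage = NULL,
                        perspective = c("societal", "payer")) {
  stopifnot(discount_rate >= 0)
  structure(list(discount_rate = discount_rate,
                 reference_year = reference_year,
                 daily_wage = daily_wage,
                 perspective = match.arg(perspective)),
            class = "econ_params")
}

#' Productivity loss (presenteeism proxy)
#'
#' `daily wage x (1 - utility weight) x duration (days)`; accrues regardless
#' of age or employment status.
#'
#' @param daily_wage USD/day.
#' @param utility_weight Health-state utility in [0, 1].
#' @param duration_days Duration of the outcome, days (>= 0).
#' @return USD (vectorized).
#' @examples
#' productivity_loss(200, 0.8, 10)  # 400
#' @export
productivity_loss <- function(daily_wage, utility_weight, duration_days) {
  stop_if_not_prob(utility_weight, "utility weight")
  stopifnot(all(duration_days >= 0))
  daily_wage * (1 - utility_weight) * duration_days
}

#' Discount to net present value
#'
#' `amount / (1 + rate)^years` (works for dollars or QALYs).
#'
#' @param amount Value(s) to discount.
#' @param years_from_reference Years after the reference year (>= 0).
#' @param params An `econ_params`.
#' @return Discounted value(s).
#' @export
discount <- function(amount, years_from_reference, params = econ_params()) {
  stopifnot(all(years_from_reference >= 0))
  amount / (1 + params$discount_rate)^years_from_reference
}

#' Summarize a life-course record into economic outcomes
#'
#' Maps each lived year of a sampled [lifecourse_record()] to its state
#' medical cost, event costs, utility (state utility minus event disutilities,
#' floored at zero), and productivity loss (wage presenteeism proxy over the
#' year), discounts everything to the reference year, and totals.  Childhood
#' years accrue utility 1 and no medical cost by default, so they cancel in
#' any paired contrast and are not included here.
#'
#' @param record A `lifecourse_record`.
#' @param params A `markov_param_set`.
#' @param econ An `econ_params`.
#' @param years_to_18 Years from the reference year to the agent's 18th
#'   birthday (discounting offset; default 0 values flows at age 18).
#' @return An `econ_summary` list: `direct_usd`, `productivity_usd`,
#'   `qalys`, `life_years`, and `total_usd` under the chosen perspective.
#' @export
summarize_econ <- function(record, params, econ = econ_params(),
                           years_to_18 = 0) {
  stopifnot(inherits(record, "lifecourse_record"))
  wage <- econ$daily_wage %||% params$daily_wage
  ages <- record$path$age
  n <- length(ages)
  direct <- prod_loss <- qalys <- 0
  if (n > 0) {
    sx <- match(record$sex, SEX_LEVELS)
    t_yr <- years_to_18 + (ages - 18)
    df <- 1 / (1 + econ$discount_rate)^t_yr
    aidx <- pmin(ages - 17L, length(params$ages))
    st <- record$path$state
    ev <- record$path$events
    util <- pmax(params$utility[st] - as.numeric(ev %*% params$event_disutility), 0)
    direct <- sum(df * (params$state_cost[cbind(st, aidx, sx)] +
                          as.numeric(ev %*% params$event_cost)))
    qalys <- sum(df * util)
    prod_loss <- sum(df * productivity_loss(wage, util, DAYS_PER_YEAR))
  }
  out <- list(direct_usd = direct, productivity_usd = prod_loss,
              qalys = qalys, life_years = record$life_years,
              total_usd = if (econ$perspective == "payer") direct
                          else direct + prod_loss)
  class(out) <- "econ_summary"
  out
}
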