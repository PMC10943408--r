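LEDGER_METRICS <- c(
  "ow_ob_cases", "disease_cases",
  paste0("events_", EVENT_TYPES),
  "deaths_total", paste0("deaths_", EVENT_TYPES),
  "qalys", "life_years", "direct_usd", "productivity_usd", "societal_usd"
)

#' Run configuration for paired scenario experiments
#'
#' @param n_agents Agents per replicate (default desk scale 50 000).
#' @param n_replicates Monte-Carlo replicates for percentile CIs (>= 2;
#'   default 20).
#' @param seed Master seed; all replicate/parameter seeds derive from it.
#' @param pa_day_sd_individual Individual PA-day dispersion, days/week.
#' @param adult_mode `"expectation"` (default): adult outcomes are exact
#'   conditional expectations given the age-18 BMI category, computed by
#'   matrix-product occupancy -- unbiased for every reported mean and free of
#'   adult-phase Monte-Carlo noise.  `"simulate"` samples each agent's life
#'   course (common random numbers across arms).
#' @param max_age Adult censoring age.
#' @param count_recurrent Count repeat events of the same type (simulate mode).
#' @param econ An `econ_params`.
#' @param metabolic A `metabolic_params`.
#' @return A `run_config` list.
#' @export
run_config <- function(n_agents = 50000L, n_replicates = 20L, seed = 1L,
                       pa_day_sd_individual = 1.5,
                       adult_mode = c("expectation", "simulate"),
                       max_age = 100, count_recurrent = FALSE,
                       econ = econ_params(), metabolic = metabolic_params()) {
  stopifnot(n_replicates >= 1)
  structure(list(n_agents = as.integer(n_agents),
                 n_replicates = as.integer(n_replicates), seed = seed,
                 pa_day_sd_individual = pa_day_sd_individual,
                 adult_mode = match.arg(adult_mode), max_age = max_age,
                 count_recurrent = count_recurrent,
                 econ = econ, metabolic = metabolic),
            class = "run_config")
}

#' Population-weighted baseline overweight/obesity prevalence
#'
#' @param table A `strata_table`.
#' @return Percent: the population-weighted mean of overweight + obesity
#'   prevalence over the 24 strata.
#' @examples
#' baseline_prevalence(load_table1())  # 35.6
#' @export
baseline_prevalence <- function(table) {
  sum(table$population * (table$overweight_prev + table$obesity_prev)) /
    sum(table$population)
}

# National weighted stratum tallies for one simulated arm.
arm_tallies <- function(arm, adult) {
  n <- nrow(arm)
  tall <- matrix(0, n, length(LEDGER_METRICS),
                 dimnames = list(NULL, LEDGER_METRICS))
  tall[, "ow_ob_cases"] <- arm$weight_class_18 %in% c("overweight", "obese")
  ev <- adult$events
  tall[, paste0("events_", EVENT_TYPES)] <- ev
  tall[, "disease_cases"] <- rowSums(ev)
  tall[, "deaths_total"] <- adult$deaths_total
  tall[, paste0("deaths_", EVENT_TYPES)] <- adult$deaths_cause
  tall[, "qalys"] <- adult$qaly
  tall[, "life_years"] <- adult$life_years
  tall[, "direct_usd"] <- adult$direct_usd
  tall[, "productivity_usd"] <- adult$productivity_usd
  tall[, "societal_usd"] <- adult$direct_usd + adult$productivity_usd
  w <- arm$sampling_weight
  rowsum(tall * w, arm$stratum)  # 24 x metrics (stratum order)
}

# Adult outcomes for one arm under the configured adult engine.
adult_outcomes_for_arm <- function(arm, mp, config, rep_seed) {
  sexi <- match(arm$sex, SEX_LEVELS)
  dsc <- (1 + config$econ$discount_rate)^(-arm$years_to_18)
  if (config$adult_mode == "expectation") {
    ea <- attr(mp, "expected_outcomes")
    if (is.null(ea)) ea <- expected_adult_outcomes(mp, config$econ, config$max_age,
                                                   config$count_recurrent)
    e <- match(arm$weight_class_18, c("normal", "overweight", "obese"))
    pick <- function(metric) ea[cbind(e, sexi, match(metric, dimnames(ea)[[3]]))]
    list(qaly = pick("qaly") * dsc,
         life_years = pick("life_years"),
         direct_usd = pick("direct_usd") * dsc,
         productivity_usd = pick("productivity_usd") * dsc,
         events = sapply(EVENT_TYPES, function(k) pick(paste0("events_", k))),
         deaths_cause = sapply(EVENT_TYPES, function(k) pick(paste0("deaths_", k))),
         deaths_total = pick("deaths_total"))
  } else {
    ent <- entry_state(arm$weight_class_18, mp)
    sim <- simulate_adult_cohort(ent, sexi, mp, config$econ, rep_seed,
                                 config$max_age, config$count_recurrent)
    list(qaly = sim$qaly * dsc, life_years = sim$life_years,
         direct_usd = sim$direct_usd * dsc,
         productivity_usd = sim$productivity_usd * dsc,
         events = sim$events, deaths_cause = sim$deaths_cause,
         deaths_total = as.numeric(sim$dead))
  }
}

#' Paired baseline/counterfactual run
#'
#' For each replicate, builds a fresh cohort, simulates childhood under the
#' baseline (`reduction_fraction = 0`, no compensation) and the counterfactual
#' scenario with identical random streams (common random numbers), runs the
#' adult engine on both arms, scales all tallies by sampling weights to
#' national counts, and records per-stratum averted quantities
#' (baseline - counterfactual).  Confidence intervals are percentile intervals
#' over replicates.
#'
#' @param scenario A `scenario_spec`.
#' @param config A `run_config`.
#' @param table A `strata_table` (defaults to the packaged fixture).
#' @param growth,markov Optional pre-synthesized parameter objects (derived
#'   from `config$seed` when omitted).
#' @return An `outcome_ledger`: list with `averted` (array replicate x
#'   stratum(24)+total x metric), `summary` (data.frame with mean and 95\% CI
#'   per stratum and metric), `scenario`, `config`, `strata`.
#' @export
run_pair <- function(scenario, config = run_config(), table = load_table1(),
                     growth = NULL, markov = NULL) {
  stopifnot(inherits(scenario, "scenario_spec"), inherits(config, "run_config"))
  if (is.null(growth)) growth <- synthesize_growth_reference(derive_seed(config$seed, "growth"))
  if (is.null(markov)) markov <- synthesize_markov_params(derive_seed(config$seed, "markov"))
  if (config$adult_mode == "expectation") {
    attr(markov, "expected_outcomes") <-
      expected_adult_outcomes(markov, config$econ, config$max_age,
                              config$count_recurrent)
  }
  nm <- length(LEDGER_METRICS)
  averted <- array(0, dim = c(config$n_replicates, 25L, nm),
                   dimnames = list(NULL, c(paste0("stratum_", 1:24), "total"),
                                   LEDGER_METRICS))
  for (rep in seq_len(config$n_replicates)) {
    rs <- derive_seed(config$seed, "rep", rep)
    coh <- build_cohort(table, growth,
                        cohort_spec(config$n_agents,
                                    config$pa_day_sd_individual, seed = rs))
    base_spec <- scenario_spec(0, offday_minutes = scenario$offday_minutes,
                               compensation_mode = "none", seed = rs)
    scen_spec <- scenario
    scen_spec$seed <- rs
    arm_b <- simulate_childhood(coh, table, growth, base_spec, config$metabolic)
    arm_s <- simulate_childhood(coh, table, growth, scen_spec, config$metabolic)
    ad_b <- adult_outcomes_for_arm(arm_b, markov, config, rs)
    ad_s <- adult_outcomes_for_arm(arm_s, markov, config, rs)
    tb <- arm_tallies(arm_b, ad_b)
    ts <- arm_tallies(arm_s, ad_s)
    diff <- tb - ts
    # QALYs and life-years are "saved" (gained by the scenario); the rest are
    # "averted" (baseline minus counterfactual).
    gained <- c("qalys", "life_years")
    diff[, gained] <- -diff[, gained]
    averted[rep, 1:24, ] <- diff
    averted[rep, 25, ] <- colSums(diff)
  }
  summary <- summarize_ledger(averted, table)
  structure(list(averted = averted, summary = summary, scenario = scenario,
                 config = config, strata = table),
            class = "outcome_ledger")
}

summarize_ledger <- function(averted, table) {
  nm <- dim(averted)[3]
  rows <- expand.grid(stratum = dimnames(averted)[[2]],
                      metric = dimnames(averted)[[3]],
                      stringsAsFactors = FALSE)
  mean_ <- lo <- hi <- numeric(nrow(rows))
  for (i in seq_len(nrow(rows))) {
    x <- averted[, rows$stratum[i], rows$metric[i]]
    mean_[i] <- mean(x)
    qq <- stats::quantile(x, c(0.025, 0.975), names = FALSE, type = 7)
    lo[i] <- qq[1]; hi[i] <- qq[2]
  }
  lab <- c(paste(table$sex, table$age_band, table$fpl), "total")
  rows$label <- lab[match(rows$stratum, c(paste0("stratum_", 1:24), "total"))]
  data.frame(rows, mean = mean_, ci_lo = lo, ci_hi = hi,
             stringsAsFactors = FALSE)
}

#' @export
print.outcome_ledger <- function(x, ...) {
  tot <- x$summary[x$summary$stratum == "total", ]
  cat(sprintf("Outcome ledger: reduction %.0f%%, off-day %g min, compensation %s\n",
              100 * x$scenario$reduction_fraction, x$scenario$offday_minutes,
              x$scenario$compensation_mode))
  cat(sprintf("  (%d agents x %d replicates, adult mode: %s)\n",
              x$config$n_agents, x$config$n_replicates, x$config$adult_mode))
  for (m in c("ow_ob_cases", "disease_cases", "qalys", "societal_usd")) {
    r <- tot[tot$metric == m, ]
    cat(sprintf("  %-14s averted/saved: %12.0f (95%% CI %.0f to %.0f)\n",
                m, r$mean, r$ci_lo, r$ci_hi))
  }
  invisible(x)
}

#' Total averted value for a metric
#'
#' @param ledger An `outcome_ledger`.
#' @param metric One of the ledger metrics (see `summary$metric`).
#' @return Mean national total (baseline - counterfactual) over replicates.
#' @export
ledger_total <- function(ledger, metric = "societal_usd") {
  s <- ledger$summary
  s$mean[s$stratum == "total" & s$metric == metric]
}

#' OLS slope of societal savings against disparity-reduction percentage
#'
#' @param reduction_pct Reduction levels in percent (e.g. `c(25, 50, 75, 100)`).
#' @param societal_usd Societal savings in US dollars at each level.
#' @return Slope in millions of dollars per percentage point.
#' @examples
#' savings_slope(c(25, 50, 75, 100), c(4.34, 8.17, 12.75, 15.60) * 1e9)  # 153.44
#' @export
savings_slope <- function(reduction_pct, societal_usd) {
  stopifnot(length(reduction_pct) >= 2,
            length(reduction_pct) == length(societal_usd))
  unname(stats::coef(stats::lm(I(societal_usd / 1e6) ~ reduction_pct))[2])
}

#' Sweep disparity-reduction fractions
#'
#' Runs [run_pair()] at each fraction (shared seeds: common random numbers
#' across the whole sweep) and reports the OLS slope of mean societal savings
#' versus reduction percentage.
#'
#' @param fractions Reduction fractions in [0, 1] (>= 2 values).
#' @param config A `run_config`.
#' @param scenario_template A `scenario_spec` providing off-day minutes and
#'   compensation settings.
#' @param table A `strata_table`.
#' @return List with `ledgers` (named by fraction), `savings_usd`, and
#'   `slope_musd_per_pct`.
#' @export
disparity_sweep <- function(fractions = c(0.25, 0.5, 0.75, 1),
                            config = run_config(),
                            scenario_template = scenario_spec(1),
                            table = load_table1()) {
  stopifnot(length(fractions) >= 2)
  growth <- synthesize_growth_reference(derive_seed(config$seed, "growth"))
  markov <- synthesize_markov_params(derive_seed(config$seed, "markov"))
  ledgers <- lapply(fractions, function(r) {
    sc <- scenario_template
    sc$reduction_fraction <- r
    run_pair(sc, config, table, growth = growth, markov = markov)
  })
  names(ledgers) <- paste0(100 * fractions, "%")
  savings <- vapply(ledgers, ledger_total, numeric(1), metric = "societal_usd")
  list(ledgers = ledgers, savings_usd = savings,
       slope_musd_per_pct = savings_slope(100 * fractions, savings))
}

#' Write ledger reports to disk
#'
#' Writes a long-format CSV (scenario x metric x stratum with mean and 95\%
#' CI), a machine-readable JSON summary, and a seed/configuration log.
#'
#' @param ledgers A list of `outcome_ledger`s (possibly empty), named by
#'   scenario.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(ledgers, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (nm in names(ledgers)) {
    s <- ledgers[[nm]]$summary
    if (nrow(s)) s <- data.frame(scenario = nm, s, stringsAsFactors = FALSE)
    rows[[nm]] <- s
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(scenario = character(), stratum = character(),
               metric = character(), label = character(),
               mean = numeric(), ci_lo = numeric(), ci_hi = numeric())
  csv_path <- file.path(dir, "outcomes_averted.csv")
  utils::write.csv(tab, csv_path, row.names = FALSE)
  json_path <- file.path(dir, "summary.json")
  jsonlite::write_json(
    lapply(ledgers, function(l) list(
      scenario = unclass(l$scenario),
      totals = l$summary[l$summary$stratum == "total",
                         c("metric", "mean", "ci_lo", "ci_hi")]
    )),
    json_path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  log_path <- file.path(dir, "run_log.json")
  jsonlite::write_json(
    lapply(ledgers, function(l) list(
      seed = l$config$seed, n_agents = l$config$n_agents,
      n_replicates = l$config$n_replicates,
      adult_mode = l$config$adult_mode,
      scenario = unclass(l$scenario))),
    log_path, auto_unbox = TRUE, digits = NA)
  invisible(c(csv_path, json_path, log_path))
}
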