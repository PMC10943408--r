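---
title: "Methods: a youth PA-disparity microsimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a youth PA-disparity microsimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paequity)
```

# Overview

`paequity` couples three stages: a **daily childhood energy-balance model**
(ages 6–18), an **annual adult multi-state Markov model** (18–100), and an
**economic layer** (discounted costs and QALYs). A scenario engine runs
paired baseline/counterfactual simulations under common random numbers (CRN)
and aggregates averted outcomes to national scale with survey sampling
weights. This vignette records the model's assumptions, the parameters that
matter, and the design decisions taken where the published description left
the design open.

# Input data

The only empirical input is the packaged 24-stratum table (sex × age band
6–10/11–13/14–17 × four FPL categories) from the 2021 National Survey of
Children's Health: population counts, mean (SE) days/week with ≥60 min of
PA, and overweight/obesity prevalence. Two derived quantities are exact
arithmetic on that table and anchor the acceptance report: the
population-weighted baseline overweight/obesity prevalence (35.6%) and each
sex/age group's scenario target (the maximum PA mean over its four FPL
categories, e.g. 4.39 days/week for boys 6–10, attained by the ≥400% FPL
stratum in every group).

The printed SEs are *survey* standard errors of stratum means, not
person-level dispersion. Individual mean PA days are therefore drawn from a
truncated normal on [0, 7] with a free dispersion parameter
(`pa_day_sd_individual`, default 1.5 days/week — a deliberately generous
person-level spread given stratum means of 2.4–4.4). The truncation would
bias the stratum mean upward if the printed mean were used as the location
parameter, so the location is solved (bisection) such that the *truncated*
mean equals the printed mean; stratum-mean recovery is then a testable
property rather than an approximation.

# Childhood energy balance

**Weekly PA.** Each week an agent draws `Binomial(7, μ/7)` active days —
bounded, integer, and mean-matching, which is all the source constrains.
Active days carry 60 minutes of MVPA; other days carry `offday_minutes`
(default 30, sensitivity 0–45). Draws convert a shared uniform per
(agent, week) through the binomial quantile function, so a larger mean can
never produce fewer active days under CRN — scenario monotonicity holds
pathwise, not just in expectation.

**Energy budget.** `EE = RMR(L) + A₀ + c · W · minutes`, with RMR affine in
fat-free mass `L` (intercepts 520/480 kcal/day male/female, slope 22
kcal/day/kg — Cunningham-like magnitudes), a flat non-MVPA allowance
`A₀ = 400` kcal/day, and a net MVPA cost `c = 0.1` kcal/kg/min (≈ a 4–5 MET
activity net of rest). `c` is the single most consequential free parameter:
it converts activity-day differences into calories and hence into all
downstream contrasts; it is config-exposed and flat across ages.

**Mass dynamics.** A daily surplus `S = intake − EE` becomes
`ΔF = 0.75·S/9441` kg fat and `ΔL = 0.25·S/1816` kg lean. The fixed
75/25 partition is an acknowledged simplification of dynamic energy-balance
models; it preserves the defining contract (daily surplus → mass, exactly
energy-conserving) and makes conservation testable to 1e-6 relative. Mass
floors (2 kg fat, 10 kg lean) clamp pathological trajectories with a logged
count; clamping is the one place conservation can be violated, deliberately.

**Intake policy (calibration).** The baseline behavioral assumption is that
children eat to *maintain their BMI percentile* at their baseline PA level.
`calibrate_intake()` finds, by bisection on [500, 6000] kcal/day, the
constant intake whose 28-day forward simulation moves the BMI percentile by
< 0.1 points (failure outside the bracket is a hard error naming the agents).
A single constant cannot hold the percentile for years in a growing child —
maintenance needs rise with growth — so the *policy* is rolling: the engine
recomputes the maintenance intake along the deterministic
percentile-maintaining trajectory every day (equivalently, the 28-day
calibration applied with vanishing window). The closed-loop tests verify the
fixed point: one year of the rolling policy drifts < 1 percentile point, and
the full run to age 18 stays within 2 points. Counterfactual arms keep the
*baseline* intake schedule (plus any compensation), so added PA creates a
deficit.

**Compensation (sensitivity axis).** `none` (default); `fraction_of_extra`
adds `c_comp ×` the realized extra MVPA expenditure relative to the paired
baseline draws (0.25 or 0.50 — compensatory eating); `diet_improvement`
subtracts 2% of the baseline intake (healthier diet accompanying more PA).

# Growth reference (synthetic stand-in)

Heights follow a logistic-pubertal-spurt-on-linear-trend curve per sex
(~116 cm at 6, ~176/163 cm male/female at 18; spurt centered at 13.5/11.5
years), and BMI at each (sex, age) is log-normal with a median rising from
~15.4 to ~21.5 kg/m² and a log-scale SD widening 0.10 → 0.20 (right-skew
grows through adolescence). Overweight/obesity thresholds are the 85th/95th
percentiles of that distribution, with half-open bands that classify
boundary values upward (stated because the source is silent). The generator
is seeded (±0.5% parameter jitter; identical seeds ⇒ identical tables) and
is *not* fitted to real CDC LMS tables — any object exposing the same fields
(per-day height, velocity, BMI meanlog/sdlog, thresholds) can replace it.
Consequently a green test establishes internal consistency (percentile
round-trips, threshold ordering, monotone growth), not anthropometric
realism.

# Adult Markov model (synthetic stand-in)

The 15-state topology is a declared stand-in — the source states only the
count and the entry rule: 3 BMI categories × 4 risk tiers (metabolically
healthy, moderate risk, high risk, diseased) + two shared post-event states
+ absorbing death. Entry is the healthy state of the BMI category at 18;
weight change that does not cross a category boundary changes nothing (the
conservative rule).

The annual law, shared verbatim by the sampler and the analytic oracle:
transition sampled from the (state, age, sex) row (row death = Gompertz
background mortality × state hazard multipliers); survivors draw each event
type from the *post-transition* state; case fatality is evaluated in fixed
type order (CHD, stroke, T2D, cancer) and the first fatal event wins; the
year's accruals (state cost, event costs, utility minus event disutilities,
presenteeism) belong to agents alive after the transition. Event
probabilities carry an enforced BMI gradient (normal ≤ overweight ≤ obese at
fixed tier/age/sex) — the one substantive structural claim the source makes
about these tables. Costs ($400–$16k/state-year, $9k–$45k/event), utilities
(0.55–0.93), and the $180 daily wage are order-of-magnitude placeholders;
utilities are age-flat and chosen so the worst state minus all four event
disutilities stays positive, which keeps the QALY floor inactive and the
expectation oracle exact. Seeded multiplicative jitter (σ = 3%) is applied
at the base-parameter level, never to the BMI multipliers, so invariants
survive every seed (property-tested over 100 seeds).

**Expectation mode.** `run_pair()` defaults to computing each agent's adult
outcomes as exact conditional expectations given (entry category, sex) by
matrix-product occupancy, including first-onset event counts via auxiliary
"no event of type k yet" occupancy vectors. This is Rao-Blackwellisation
over the adult phase: unbiased for every reported mean, it removes the
adult-phase Monte-Carlo noise that produces sign-flipping cells in sampled
designs, and makes scenario orderings testable at desk scale. Sampled life
courses (`adult_mode = "simulate"`, CRN streams keyed by seed/year/purpose)
remain available and are tested against the same oracle.

# Economics

3%/year discounting to 2023 (the cohort start — the anchor is a package
choice; the source fixes the rate but not the anchor), 2023 USD. Payer =
direct medical; societal = direct + presenteeism
(`wage × (1 − utility) × days`, accrued at every age). Childhood years carry
utility 1 and no medical cost by default (a config switch exists), so they
cancel in all paired contrasts. Each agent's adult stream is valued at age
18 and rescaled by `(1.03)^(−years_to_18)`, which is exact because
discounting is linear.

# Scenario engine and uncertainty

Baseline and counterfactual share the cohort and every random stream, so
`r = 0` reproduces the baseline *bit for bit* and all averted quantities are
exactly zero — the null identity is a test, not a statistic. Overweight/
obesity cases averted are measured as weighted headcount differences in BMI
category at age 18 (under the maintenance policy the baseline category is
constant up to bounded weekly noise, so this matches the 6–17 prevalence
framing). Replicate-level percentile intervals (default 20 replicates of
50 000 agents; tests use smaller, stated scales) capture cohort-sampling and
childhood-path variation.

# Numerical choices

- Largest-remainder apportionment allocates agents to strata; ties break in
  printed stratum order. Sampling weights are population/agents-per-stratum,
  so weighted totals are exact by construction.
- Bisection tolerances: intake calibration 0.1 percentile points over 28
  days (≤ 45 iterations); truncated-normal mean-matching 1e-10.
- Baseline BMI percentiles are drawn uniform within class bands (2–85,
  85–95, 95–99.8) — the 99.8 cap avoids the log-normal's extreme tail.
- Body composition initializes from class- and sex-specific fat fractions
  (0.20/0.25, 0.28/0.32, 0.35/0.40 male/female), config-exposed; no
  initialization rule is published.
- Transition-row construction caps non-stay mass at 0.98 before computing
  the diagonal, so rows sum to 1 within 1e-12 at every age/sex/seed.
- The occupancy acceptance check compares ~1100 correlated year × state
  cells; the 3-SE rule is applied at the familywise level
  (Bonferroni-adjusted per-cell threshold ≈ 4.7 SE, plus a mean-|z| < 1.5
  bound). A raw per-cell 3-SE bound rejects an exactly-correct law about
  half the time at this cell count; the adjusted test still rejects a 0.01
  perturbation of a single transition by three orders of magnitude.

# What a green suite does and does not establish

Green tests establish: the Table-derived quantities (35.6% baseline
prevalence, 4.39-day target, $153.4M/pct slope) to printed precision;
parameter recovery of all 24 strata at 3 Monte-Carlo SEs; exact CRN nulls;
pathwise monotonicity in the reduction fraction; the directional sensitivity
orderings (off-day minutes 0 > 15 > 30 > 45; diet −2% > none > 25% > 50%
compensation); energy conservation; the calibration fixed point; and
simulation/oracle agreement in the adult model. They do **not** establish
national dollar or case magnitudes: those flow through the synthetic
stand-in disease and cost tables and are order-of-magnitude illustrations
until the real supplementary tables are substituted (every generator is
swappable behind its type).

# Known limitations

- No race/ethnicity dimension (the source names this as its own limitation),
  no household structure, geography, or school assignment.
- Non-weight pathways from PA to health (bone density, mental health) are
  excluded, as in the source; savings are conservative in that respect.
- Fixed energy partition rather than dynamic energy-balance ODEs; no
  adaptive thermogenesis; growth-associated energy cost is folded into the
  maintenance-intake calibration rather than modeled explicitly.
- Adult BMI category is frozen at its age-18 value; no adult weight
  dynamics, treatment effects, or secular incidence trends.
- Recurrent events are excluded from case counts by default
  (`count_recurrent` switches both engines consistently).
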