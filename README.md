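# paequity

Agent-based microsimulation of the health and economic value of reducing
socioeconomic disparities in physical activity (PA) among US children and
adolescents aged 6–17.

## The problem

US youth in lower-income households (measured against the federal poverty
level, FPL) average fewer days per week with ≥60 minutes of physical activity
than their higher-income peers in the same sex and age group. Less activity
during childhood means more overweight and obesity at the end of adolescence,
which raises lifetime risk of type 2 diabetes, coronary heart disease (CHD),
stroke, and cancer — and the medical costs, productivity losses, and lost
quality-adjusted life-years (QALYs) that follow. `paequity` asks the
counterfactual question: *what would be averted if every sex × age × FPL
stratum were raised part way, or all the way, to the most-active stratum in
its sex/age group?*

## The model

Each child is a computational agent with sex, age (in days), FPL category,
height, fat mass *F*, fat-free mass *L*, and an individual mean of active
days/week. The simulation has three coupled stages:

1. **Childhood energy balance (daily, to age 18).** Each week the agent draws
   `a ~ Binomial(7, μ/7)` active days (60 min of MVPA; other days get 30 min,
   varied 0–45 in sensitivity analyses). Daily expenditure is
   `EE = RMR(L) + A₀ + c·W·minutes` with net MVPA cost `c = 0.1` kcal/kg/min.
   Intake is calibrated so that, at *baseline* PA, the agent's BMI percentile
   stays constant as it grows along the growth reference; the daily surplus
   `S = intake − EE` becomes mass via a fixed 75/25 fat/lean partition with
   tissue energy densities 9441/1816 kcal/kg. Raising PA while holding intake
   at its baseline-calibrated path therefore produces a deficit and weight
   loss.
2. **Adult multi-state Markov model (annual, 18 to 100).** Entry at the
   metabolically healthy state of the agent's BMI category at 18 (85th/95th
   BMI-percentile cutoffs; category unchanged ⇒ risks unchanged — the
   conservative rule). Fifteen states (3 BMI categories × 4 risk tiers, two
   post-event states, death) with state-, age-, and sex-specific transition,
   event (CHD, stroke, type 2 diabetes, cancer), and case-fatality
   probabilities. The published model keeps these tables in an unpublished
   supplement, so `paequity` generates seeded **synthetic stand-ins** that
   satisfy every structural invariant (rows sum to 1, death absorbing, event
   risk non-decreasing in BMI category).
3. **Economics.** Payer perspective: direct medical costs. Societal adds the
   presenteeism proxy `daily wage × (1 − utility) × duration`. Everything is
   discounted at 3%/year to 2023 and expressed in 2023 USD.

Scenarios shift each stratum's mean active days by
`r · (max over FPL in the sex/age group − stratum mean)`, `r ∈ {0.25, 0.5,
0.75, 1}`, with common random numbers across the baseline/counterfactual pair
so that `r = 0` is *exactly* null and contrasts carry no shared noise.
National totals come from survey sampling weights (the 24-stratum table of
the 2021 National Survey of Children's Health ships as a fixture covering
49.9M children).

## Worked example

```r
library(paequity)
tab <- load_table1()
baseline_prevalence(tab)        # 35.6  (% overweight+obese, weighted)
target_level(tab, "male", "6-10")  # 4.39 days/week (the boys-6-10 target)

cfg <- run_config(n_agents = 2000, n_replicates = 3, seed = 1)
led <- run_pair(scenario_spec(reduction_fraction = 1), cfg)
led
#> Outcome ledger: reduction 100%, off-day 30 min, compensation none
#>   (2000 agents x 3 replicates, adult mode: expectation)
#>   ow_ob_cases    averted/saved:       515209 (95% CI 400156 to 707922)
#>   disease_cases  averted/saved:       181424 (95% CI 165539 to 197887)
#>   qalys          averted/saved:      1212627 (95% CI 1088749 to 1326266)
#>   societal_usd   averted/saved:  78781476771 (95% CI 70712873961 to 86195775264)
```

Reading this: fully eliminating the PA disparity averts ~515 000 national
overweight/obesity cases at age 18 and ~181 000 lifetime weight-related
disease cases, saving ~$79B (societal, discounted). *Magnitudes downstream of
the adult model depend on the synthetic stand-in parameter tables and are
order-of-magnitude illustrations, not estimates* — the published study, with
its real supplement tables, reports $15.6B and 383 000 cases for this
scenario. Orderings and signs (monotonicity in `r`, sensitivity orderings in
off-day minutes and dietary compensation) are structural and are what the
test suite asserts.

A CLI mirror lives in `inst/scripts/simulate.R`
(`--reduction`, `--offday-minutes`, `--compensation {none,frac:0.25,frac:0.5,diet:-0.02}`,
`--n-agents`, `--replicates`, `--seed`, `--perspective`, `--out`, `--sweep`).

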