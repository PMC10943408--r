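Package: paequity
Title: Microsimulation of Socioeconomic Disparities in Youth Physical Activity
Version: 0.1.0
Authors@R:
    person("paequity", "Authors", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Agent-based microsimulation of the health and economic value of
    reducing socioeconomic disparities in physical activity among US children
    and adolescents. Couples a daily energy-balance childhood growth model to
    an annual multi-state Markov model of adult weight-related disease, with a
    counterfactual scenario engine (common random numbers) that quantifies
    overweight/obesity cases averted, weight-related disease cases and deaths
    averted, quality-adjusted life-years saved, and discounted payer and
    societal cost savings. National survey strata (population, activity days
    per week, overweight and obesity prevalence by sex, age band, and federal
    poverty level) ship as a packaged fixture; supplementary growth and
    disease-parameter tables are generated as seeded synthetic stand-ins.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
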