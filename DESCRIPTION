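Package: pouchcea
Title: Markov Cohort Cost-Effectiveness Models for Probiotic Prophylaxis of Pouchitis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-time Markov cohort models evaluating an 8-strain probiotic
    for primary prevention of pouchitis and secondary prevention of pouchitis
    relapse after ileal pouch-anal anastomosis, against no prophylaxis. Provides
    a typed registry of model parameters with triangular Monte Carlo ranges, a
    generic cohort engine with tunnel states, transition-triggered costs and
    annual-rate discounting, incremental cost-effectiveness (ICER, net monetary
    benefit, dominance classification), one-way sensitivity analysis with
    threshold bisection, probabilistic sensitivity analysis with
    cost-effectiveness acceptability curves, and a patient-level
    microsimulation oracle for validating the cohort engine.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
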