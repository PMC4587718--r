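Package: afcea
Title: Cost-Effectiveness of Genetic Testing to Motivate Warfarin
    Adherence in Atrial Fibrillation
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Decision-analytic Markov cohort model comparing usual care
    (aspirin) with a 4q25 genetic-testing strategy intended to motivate
    warfarin adherence among atrial-fibrillation patients who declined
    warfarin.  Computes discounted costs, quality-adjusted life-years and
    incremental cost-effectiveness ratios over a five-year horizon,
    adherence thresholds for cost-effectiveness and cost saving, one-way
    (tornado) and probabilistic sensitivity analyses with triangular
    distributions, CHADS2 stroke-rate stratification, and an
    individual-level microsimulation that serves as a validation oracle
    for the cohort engine.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
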