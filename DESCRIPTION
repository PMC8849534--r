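Package: allostasim
Title: Stochastic Simulation of the Work-Stress, Cortisol and
    Allostatic-Load Pathway to Disease
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates the physiological pathway from work stressors to
    disease. Poisson-distributed neural impulses (circadian night impulses
    clustered before waking, work impulses spread over working hours) drive
    a first-order cortisol equation; cortisol loads a reversible allostatic
    strain variable; strain in excess of an allostatic threshold accrues
    irreversible allostatic load; load beyond a disease threshold flips a
    disease state. Provides population samplers for correlated and
    uncorrelated impulse-rate scenarios, diurnal cortisol summaries (AUCg,
    AUCi, wake-to-bed slope), odds ratios of disease per standard deviation
    of work-stressor exposure, parameter-robustness sweeps, and relative
    disease risk across workweek configurations (compressed and spread-out
    weeks) under common random numbers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
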