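Package: oxialarm
Title: Simulation and Paired Analysis of SpO2 Alarm Strategies During Automated Oxygen Control
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to study pulse-oximetry (SpO2) alarm strategies in neonates
    managed with closed-loop FiO2 control. Provides a synthetic generator of
    5-second SpO2/FiO2 monitoring logs with desaturation and hyperoxemia
    events, signal dropouts and a simple controller emulation; a
    threshold-plus-persistence-delay alarm engine; oxygen-exposure outcome
    metrics (extreme-SpO2 prevalence, prolonged episodes, normoxemia, hourly
    median summaries, histograms); paired crossover statistics (Wilcoxon
    signed-rank, paired t, Hodges-Lehmann median-difference confidence
    intervals, Monte-Carlo power); and an end-to-end randomized crossover
    study pipeline with balanced-block first-day randomization and
    protocol-violation screening.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
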