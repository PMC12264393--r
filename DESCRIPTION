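Package: broodparasim
Title: Individual-Based Stochastic-Reinforcement Simulation of Cuckoo-Host Brood Parasitism
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the coevolutionary arms race between an obligate avian
    brood parasite (the common cuckoo) and its host species as an
    individual-based stochastic model with experience-driven reinforcement of
    behavioural probabilities. Individuals carry heritable trait probabilities
    (egg-colour, egg-shape and vocal mimicry or detection, laying and
    nest-guarding success, fertility, rearing success) drawn from truncated
    distributions by acceptance-rejection sampling; the annual cycle covers
    pairing, clutch and parasite egg generation, parasitism with preferred-host
    targeting and optional back-up host switching, egg detection, incubation
    with four terminal nest states, vocal-password chick rejection,
    logistic-regulated rearing, reinforcement and cohort turnover. Experiment
    drivers reproduce habitat-loss-and-fragmentation scenarios, back-up
    behaviour contrasts, rejection-rate grid sweeps, sensitivity analyses and
    replicate ensembles with seed-reproducible summaries, plus validation
    metrics against observed parasitism-ratio series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
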