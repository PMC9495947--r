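Package: refugeCA
Title: Cellular-Automaton Simulation of Insecticide-Resistance Evolution
    under Larval Competition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-time, probabilistic cellular-automaton model of
    insecticide-resistance evolution in Spodoptera frugiperda and
    Helicoverpa armigera larvae competing in non-Bt refuge crops (cotton,
    corn, soybean). Competition outcomes are governed by strain-vs-strain
    five-day survival payoff matrices estimated from larval bioassays;
    generational genetics are biallelic with Hardy-Weinberg initialization
    and random mating within quadrant-structured adult pools. Includes a
    survival-analysis layer (Kaplan-Meier estimation and log-rank
    comparison of synthetic competition bioassays) that turns bioassay
    records into payoff-matrix entries, scenario and grid runners with
    replicated allele-frequency trajectories, and plotting of mean
    trajectories with replicate envelopes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    survival,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
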