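Package: molega
Title: Multi-Objective Genetic Algorithm for Molecular Optimization with
    Tanimoto Crowding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fragment-based multi-objective genetic algorithm for drug-like
    molecule optimization. Implements NSGA-II-style non-dominated sorting
    with a structure-aware crowding distance (mean Tanimoto distance between
    fingerprints of front mates) and a generation-dependent acceptance
    probability for the population update, together with GuacaMol-style
    multi-property objective benchmark tasks (Gaussian, one-sided Gaussian
    and thresholded-linear score modifiers), ECFP/FCFP/atom-pair
    fingerprints, Bemis-Murcko core/side-chain crossover and mutation
    operators, and run-level metrics (hypervolume against the origin,
    success rate, geometric-mean fitness, internal similarity).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
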