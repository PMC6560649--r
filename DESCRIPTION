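Package: ditras
Title: Diary-Based Simulation of Spatio-Temporal Human Mobility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage generative modelling of individual human mobility.
    A data-driven Markov "mobility diary" generator is learned from sparse
    location records (call detail records or GPS-derived stop sequences)
    and captures the circadian tendency of individuals to follow or break
    their routine. Diaries are translated into geographic trajectories over
    a weighted spatial tessellation by pluggable location-choice mechanisms:
    exploration and preferential return driven by a gravity
    origin-destination kernel (d-EPR), distance-and-popularity weighting
    (SWIM) and least-action trip planning (LATP). Includes baseline diary
    generators, preprocessing filters for raw records, a synthetic-record
    generator with planted ground truth, and a nine-measure validation
    suite (trip distance, radius of gyration, mobility entropy, location
    frequency, visits per location, locations per user, trips per hour,
    trips per day, stay time) with RMSE and Kullback-Leibler comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    geosphere,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
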