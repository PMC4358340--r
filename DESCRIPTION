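Package: infotaxr
Title: Maximally Informative Search, Drift-Diffusion Reduction, and
    Behavioral-State Segmentation for Foraging Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modeling multi-stage animal food search as maximally
    informative (infotaxis) exploration of a finite arena. Maintains a grid
    Bayesian belief over the location of an odor source together with the
    probability that the source is absent from the known area, runs the
    entropy-greedy search loop, and detects the abrupt transition from local
    to global search. Includes a one-parameter drift-diffusion reduction of
    the accumulating log-probability that food is elsewhere, a
    chemotaxis-adaptation null model, Poisson hidden Markov segmentation of
    turn-rate series from centroid tracks, and a synthetic worm-track
    generator with planted behavioral-state transitions for end-to-end
    pipeline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
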