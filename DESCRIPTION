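Package: fbmbench
Title: Simulation and Benchmarking of Heterogeneous Single-Particle Diffusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates two-dimensional fractional Brownian motion trajectories
    whose diffusive state (generalized diffusion coefficient K and anomalous
    exponent alpha) switches under five interaction models (single-state,
    multi-state Markov, transient dimerization, transient confinement in
    osmotic compartments, and quenched traps), renders them as realistic
    single-molecule fluorescence videos with an Airy point-spread function and
    Poisson noise, writes challenge-style datasets (trajectory CSV tables and
    8-bit multi-frame TIFF videos with VIP label maps), and scores changepoint,
    segment and ensemble predictions with a full metric suite: gated Hungarian
    changepoint pairing, Jaccard similarity, RMSE, mean squared logarithmic
    error on K, mean absolute error on alpha, micro-averaged F1 on diffusion
    type, first Wasserstein distance between Gaussian-mixture state
    distributions, and mean-reciprocal-rank aggregation. A non-learned MSD-fit
    baseline predictor exercises the scoring pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    clue,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
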