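Package: timeshiftr
Title: Random Time-Shift Distributions for Stochastic Population Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the distribution of the martingale limit W of supercritical
    multitype Markov branching processes and the induced random time-shift
    distribution that corrects deterministic approximations of stochastic
    population models (epidemics, within-host viral dynamics). Implements two
    routes to the law of W: a probability-estimation method based on
    error-controlled Taylor expansion of the Laplace-Stieltjes transform,
    recursive composition with embedded-process progeny generating functions and
    Abate-Whitt numerical inversion (concentrated matrix-exponential and Euler
    node families); and a moment-matching method fitting a generalised gamma
    distribution to the first five conditional moments. Includes conditional
    moment recursions, extinction probabilities, hybrid trajectory generation by
    randomly time-shifting a single deterministic solution, and exact Gillespie
    simulation for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    stats,
    tibble,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
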