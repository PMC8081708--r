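Package: seedbanklim
Title: Strong Seed Bank Diffusions, Coalescents and Their
    Separation-of-Timescales Limits
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulators and exact limit calculus for the strong seed bank
    model of population genetics. Provides the block-counting process of the
    seed bank coalescent and of the structured (two-island) coalescent as
    continuous-time Markov chains with exact transition semigroups, the seed
    bank and two-island frequency diffusions via Euler-Maruyama simulation,
    their super-evolutionary scaling limits (the ancient ancestral lines
    process with degenerate semigroup P exp(tG), and a piecewise-deterministic
    jump process simulated by exact hazard inversion), a generic
    separation-of-timescales engine for continuous-time Markov chains
    (discretisation, fast/slow decomposition, projection extraction, limit
    generator), and a moment-duality verification engine that checks forward
    and backward descriptions against each other exactly and by Monte Carlo.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
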