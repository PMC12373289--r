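Package: chanbench
Title: Benchmarking Optimisation Approaches for Cardiac Ion Channel Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A benchmarking harness for parameter optimisation of cardiac
    ion channel models under voltage-clamp protocols. Provides a suite of
    Hodgkin-Huxley and Markov benchmark problems with analytic and adaptive
    ODE forward solvers (with parameter sensitivities), a standardised
    modification layer (log/scale transforms, parameter and transition-rate
    bounds with a discontinuous penalty), per-evaluation tracking with
    cost-threshold and stagnation termination, implementations of common
    optimisers (trust-region reflective least squares, Nelder-Mead, CMA-ES,
    particle swarm, genetic algorithm, differential evolution, pattern
    search) plus a multistart trust-region approach, and performance
    statistics based on Expected Run Time with Jeffreys-prior bootstrap
    significance testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    deSolve,
    minpack.lm,
    Matrix,
    jsonlite,
    readr,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
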