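Package: goalreach
Title: Goal- and Time-Based Analysis of Decisions Under Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models repeated choice among risky prospects as a walk on a
    stage network toward a goal. A payoff table of options (utility u won
    with probability p) and a goal G define an absorbing Markov chain whose
    transition matrix is composed from the game's link probabilities and a
    decision maker's strategy weights. Iterating the chain yields the
    time-dependent probability of having reached the goal, P_com(t), which
    replaces expected utility as the decision criterion: risky and safe
    options with equal expected utility separate into early-time and
    late-time preference regimes. Includes the named strategies (fix,
    min k, max k, risky, random, safe), closed-form and fundamental-matrix
    hitting-time analysis, CDF-crossing and dominance comparison, strategy
    search over weight simplices, goal-in-mind window estimation from
    observed choices, and a seeded Monte-Carlo walker that serves as a
    stochastic cross-check of the matrix iteration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
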