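# Monte-Carlo walkers on the decision network: a stochastic cross-check of
# the matrix iteration (both must agree by the law of large numbers).

#' Simulate an ensemble of decision walks
#'
#' Runs `n_walkers` independent walkers from the start stage: each period a
#' walker at `S_i` draws an option according to the strategy weights and
#' advances with the option's probability, else stays. First arrivals at
#' the goal are recorded; walkers still unabsorbed at the horizon are
#' censored. The ensemble is simulated synchronously (all walkers advance
#' one period at a time, sampled stage-by-stage from the composed
#' transition row), which is exactly equivalent in distribution and
#' reproducible given the seed.
#'
#' @param game A [decision_game()].
#' @param strategy A `decision_strategy` or the name of one.
#' @param n_walkers Number of walkers (>= 1).
#' @param horizon Censoring horizon; `NULL` uses the analytic auto-horizon
#'   (tail mass below 1e-9).
#' @param seed Integer seed; same seed, same ensemble.
#' @param fix_utility Passed to [named_strategy()] when `strategy` is
#'   `"fix"`.
#' @return A `walk_ensemble`: list with `hitting_times` (`NA` when
#'   censored), `empirical_cdf` (tibble `t`, `ecdf`), `n_walkers`, `seed`,
#'   `horizon`. [glance()] summarises; [tidy()] returns the empirical CDF.
#' @examples
#' ens <- simulate_walks(standard_game(5), "min_k", n_walkers = 50, seed = 7)
#' unique(ens$hitting_times)
#' @export
simulate_walks <- function(game, strategy, n_walkers, horizon = NULL,
                           seed = 1, fix_utility = NULL) {
  stopifnot(inherits(game, "decision_game"))
  if (is.character(strategy)) {
    strategy <- named_strategy(game, strategy, fix_utility = fix_utility)
  }
  if (!.is_count(n_walkers)) abort("`n_walkers` must be at least 1.")
  n_walkers <- as.integer(n_walkers)
  A <- transition_matrix(game, strategy)
  absorb <- attr(A, "absorb")
  start <- attr(A, "start")
  if (is.null(horizon)) {
    horizon <- length(.cdf_vector(A, epsilon = 1e-9)) - 1L
  }

  state <- rep.int(start, n_walkers)
  hit <- rep(NA_integer_, n_walkers)
  arrivals <- integer(horizon + 1) # arrivals at exactly t = 0..horizon
  if (start == absorb) arrivals[1] <- n_walkers

  withr::with_seed(seed, {
    for (t in seq_len(horizon)) {
      alive <- which(is.na(hit))
      if (length(alive) == 0) break
      for (s in sort(unique(state[alive]))) {
        here <- alive[state[alive] == s]
        row <- A[s + 1, ]
        support <- which(row > 0) - 1L
        nxt <- if (length(support) == 1) {
          rep.int(support, length(here))
        } else {
          support[sample.int(length(support), length(here),
            replace = TRUE, prob = row[support + 1]
          )]
        }
        state[here] <- nxt
        landed <- here[nxt == absorb]
        if (length(landed) > 0) {
          hit[landed] <- t
          arrivals[t + 1] <- arrivals[t + 1] + length(landed)
        }
      }
    }
  })

  if (all(is.na(hit)) && n_walkers > 0 && start != absorb) {
    warn("No walker reached the goal within the horizon.")
  }
  structure(
    list(
      hitting_times = hit,
      n_walkers = n_walkers,
      seed = seed,
      horizon = horizon,
      empirical_cdf = tibble(
        t = 0:horizon,
        ecdf = cumsum(arrivals) / n_walkers
      ),
      strategy = strategy$name,
      signature = .game_signature(game)
    ),
    class = "walk_ensemble"
  )
}

#' @export
print.walk_ensemble <- function(x, ...) {
  cat(sprintf(
    "<walk_ensemble> %d walkers, strategy %s, horizon %d, seed %d\n",
    x$n_walkers, x$strategy, x$horizon, x$seed
  ))
  cat(sprintf(
    "absorbed: %d (%.1f%%), mean hitting time %.3f\n",
    sum(!is.na(x$hitting_times)),
    100 * mean(!is.na(x$hitting_times)),
    mean(x$hitting_times, na.rm = TRUE)
  ))
  invisible(x)
}

#' @describeIn simulate_walks Empirical CDF as a tibble.
#' @param x A `walk_ensemble`.
#' @param ... Unused.
#' @export
tidy.walk_ensemble <- function(x, ...) x$empirical_cdf

#' @describeIn simulate_walks One-row summary: walkers, censoring, mean
#'   hitting time of the absorbed walkers.
#' @export
glance.walk_ensemble <- function(x, ...) {
  tibble(
    n_walkers = x$n_walkers,
    n_censored = sum(is.na(x$hitting_times)),
    mean_hitting_time = mean(x$hitting_times, na.rm = TRUE),
    horizon = x$horizon,
    seed = x$seed
  )
}

#' Agreement between simulated and analytic curves
#'
#' Sup-norm distance between the ensemble's empirical CDF and the
#' analytic `P_com(t)`, judged against the Dvoretzky-Kiefer-Wolfowitz
#' bound `sqrt(log(2 / alpha) / (2 n))`: with probability `1 - alpha` an
#' ensemble truly drawn from the analytic law stays within it.
#'
#' @param ensemble A `walk_ensemble` (or a `goal_curve`, treated as the
#'   degenerate infinite ensemble — distance to itself is 0).
#' @param curves A `goal_curve` for the same game and strategy.
#' @param alpha Confidence parameter of the bound.
#' @return One-row tibble: `max_abs_deviation`, `bound`, `n`, `alpha`,
#'   `pass`.
#' @examples
#' sg <- standard_game(5)
#' ens <- simulate_walks(sg, "random", n_walkers = 2000, seed = 11)
#' agreement_test(ens, goal_curve(sg, "random"))
#' @export
agreement_test <- function(ensemble, curves, alpha = 0.01) {
  stopifnot(inherits(curves, "goal_curve"))
  if (inherits(ensemble, "goal_curve")) {
    emp <- tibble(t = ensemble$t, ecdf = ensemble$cdf)
    n <- Inf
    sig <- attr(ensemble, "signature")
  } else {
    stopifnot(inherits(ensemble, "walk_ensemble"))
    emp <- ensemble$empirical_cdf
    n <- ensemble$n_walkers
    sig <- ensemble$signature
  }
  sigc <- attr(curves, "signature")
  if (!is.na(sig) && !is.na(sigc) && !identical(sig, sigc)) {
    abort("Ensemble and curves come from different games.")
  }
  T_common <- min(max(emp$t), max(curves$t))
  d <- max(abs(emp$ecdf[emp$t <= T_common] - curves$cdf[curves$t <= T_common]))
  bound <- if (is.finite(n)) sqrt(log(2 / alpha) / (2 * n)) else 0
  tibble(
    max_abs_deviation = d, bound = bound, n = n, alpha = alpha,
    pass = d <= bound
  )
}
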