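# Comparing curves and strategies: interlace times, dominance, rankings,
# strategy search, goal-in-mind windows, and the inconsistency bound.

# first index (into the t grid) of strict separation; NA if the curves are
# indistinguishable within tol over the common horizon
.first_separation <- function(d, tol = .TOL_TIE) {
  idx <- which(abs(d) > tol)
  if (length(idx) == 0) NA_integer_ else idx[1]
}

#' Interlace time of two goal-reaching curves
#'
#' Two CDF curves that start apart and cross define an interlace time: the
#' smallest `t >= 1` at which the initially trailing curve first catches
#' the initially leading one. Before `t_int` the leader is preferable (for
#' urgent goals), after it the other is (for patient goals). Differences
#' smaller than `tol` are ties and are skipped, so float-order artifacts
#' cannot manufacture a crossing.
#'
#' @param x,y `goal_curve` objects on the same game.
#' @param tol Tie tolerance on CDF differences.
#' @return The interlace time as an integer, or `NA` if the curves never
#'   cross (a dominant pair, or indistinguishable curves — see the
#'   `indistinguishable` attribute).
#' @examples
#' g24 <- decision_game(
#'   data.frame(label = c("A", "C"), u = c(6, 4), p = c(1 / 3, 0.5)), 24
#' )
#' interlace_time(
#'   curve_from_matrix(reduce_fix_chain(g24, 6)),
#'   curve_from_matrix(reduce_fix_chain(g24, 4))
#' )
#' @export
interlace_time <- function(x, y, tol = .TOL_TIE) {
  cmp <- compare_curves(x, y, tol = tol)
  structure(cmp$interlace, indistinguishable = cmp$indistinguishable)
}

#' @rdname interlace_time
#' @return `compare_curves()` returns a one-row tibble with the interlace
#'   time, the leader before and after it, and an `indistinguishable` flag.
#' @export
compare_curves <- function(x, y, tol = .TOL_TIE) {
  stopifnot(inherits(x, "goal_curve"), inherits(y, "goal_curve"))
  # curves are comparable exactly when they target the same (monetary)
  # goal; the games may differ (e.g. single-option fix games per curve)
  gx <- attr(x, "goal") %||% NA_real_
  gy <- attr(y, "goal") %||% NA_real_
  if (!is.na(gx) && !is.na(gy) && abs(gx - gy) > 1e-9) {
    abort("Curves target different goals; comparison is undefined.")
  }
  nm <- c(attr(x, "strategy"), attr(y, "strategy"))
  n <- min(nrow(x), nrow(y))
  d <- y$cdf[1:n] - x$cdf[1:n]
  t <- x$t[1:n]
  sep <- .first_separation(d, tol)
  if (is.na(sep)) {
    return(tibble(
      x = nm[1], y = nm[2], interlace = NA_integer_,
      leader_before = NA_character_, leader_after = NA_character_,
      indistinguishable = TRUE
    ))
  }
  lead <- sign(d[sep]) # +1: y leads initially
  after <- which(seq_along(d) > sep & lead * d < -tol)
  cross <- if (length(after) == 0) NA_integer_ else as.integer(t[after[1]])
  tibble(
    x = nm[1], y = nm[2],
    interlace = cross,
    leader_before = if (lead > 0) nm[2] else nm[1],
    leader_after = if (is.na(cross)) {
      if (lead > 0) nm[2] else nm[1]
    } else {
      if (lead > 0) nm[1] else nm[2]
    },
    indistinguishable = FALSE
  )
}

#' Dominance between two options under the fix strategy
#'
#' Option X dominates option Y when X is at least as good on both utility
#' and probability and strictly better in expected utility: then
#' `P_comX(t) >= P_comY(t)` at every `t` and the choice is unambiguous
#' (fewer successes are needed at a no-worse per-trial rate). When
#' `(u_X - u_Y)(p_X - p_Y) < 0` the preference is time-dependent — the
#' curves interlace — and the verdict is `"none"`, as it is for equal
#' expected utilities.
#'
#' @param x,y Options: anything with elements `u` and `p` (a one-row data
#'   frame, a named list, or a named vector).
#' @return `"first"`, `"second"`, or `"none"`.
#' @examples
#' dominance(list(u = 6, p = 1 / 3), list(u = 6, p = 0.3)) # "first"
#' dominance(list(u = 6, p = 1 / 3), list(u = 4, p = 0.5)) # "none"
#' @export
dominance <- function(x, y) {
  ux <- as.numeric(x[["u"]])
  px <- as.numeric(x[["p"]])
  uy <- as.numeric(y[["u"]])
  py <- as.numeric(y[["p"]])
  ex <- ux * px
  ey <- uy * py
  # componentwise no-worse plus strictly better expected utility; when
  # (u_X - u_Y)(p_X - p_Y) < 0 the preference is time-dependent instead
  if (ux >= uy && px >= py && ex > ey) return("first")
  if (uy >= ux && py >= px && ey > ex) return("second")
  "none"
}

#' Compare several strategies on one game
#'
#' Computes the goal-reaching curve of every strategy on a common horizon,
#' every pairwise interlace time, and the CDF ranking in the early window
#' (before the first pairwise crossing) and the late window (after the
#' last). On the standard game the early ranking runs from riskiest to
#' safest and the late ranking is its exact reverse.
#'
#' @param game A [decision_game()].
#' @param strategies Character vector of named strategies, or a named list
#'   of `decision_strategy` objects.
#' @param horizon Common horizon; `NULL` extends every curve until its tail
#'   is below `epsilon`.
#' @param epsilon Tail mass for the auto-horizon.
#' @return A `strategy_comparison`: list with `curves` (long tibble),
#'   `pairwise` (tibble of [compare_curves()] rows), `early_ranking`,
#'   `late_ranking` (labels, best first) and the windows used. [tidy()]
#'   returns the pairwise table, [autoplot()] overlays the CDFs.
#' @examples
#' cmp <- compare_strategies(standard_game(10), c("max_k", "min_k"))
#' cmp$early_ranking
#' @export
compare_strategies <- function(game, strategies, horizon = NULL,
                               epsilon = 1e-9) {
  stopifnot(inherits(game, "decision_game"))
  if (is.character(strategies)) {
    strategies <- setNames(
      lapply(strategies, function(s) named_strategy(game, s)), strategies
    )
  }
  if (length(strategies) < 2) abort("Need at least two strategies.")
  if (is.null(names(strategies))) {
    names(strategies) <- vapply(strategies, function(s) s$name, "")
  }
  curves <- lapply(names(strategies), function(nm) {
    A <- transition_matrix(game, strategies[[nm]])
    attr(A, "strategy") <- nm
    curve_from_matrix(A, horizon = horizon, epsilon = epsilon)
  })
  names(curves) <- names(strategies)
  # align on a common horizon (the longest auto-horizon)
  T_max <- max(vapply(curves, nrow, 1L)) - 1L
  curves <- lapply(curves, function(cv) {
    if (nrow(cv) - 1L < T_max) {
      curve_from_matrix(
        structure(attr(cv, "matrix"), strategy = attr(cv, "strategy")),
        horizon = T_max
      )
    } else {
      cv
    }
  })

  pairs <- utils::combn(names(curves), 2, simplify = FALSE)
  pairwise <- purrr::map_dfr(pairs, function(pr) {
    compare_curves(curves[[pr[1]]], curves[[pr[2]]])
  })

  tints <- pairwise$interlace[!is.na(pairwise$interlace)]
  cdf_mat <- vapply(curves, function(cv) cv$cdf, numeric(T_max + 1))
  rank_at <- function(tt) names(sort(-cdf_mat[tt + 1, ]))
  # a ranking at t is meaningful only where the curves are numerically
  # distinguishable: drop t where any two CDFs coincide within tolerance
  # (early zeros, late saturation at 1)
  strict_at <- function(tt) {
    min(abs(diff(sort(cdf_mat[tt + 1, ])))) > .TOL_TIE
  }
  modal_ranking <- function(ts) {
    ts <- ts[vapply(ts, strict_at, TRUE)]
    if (length(ts) == 0) return(character(0))
    seqs <- vapply(ts, function(tt) paste(rank_at(tt), collapse = " > "), "")
    strsplit(names(which.max(table(seqs))), " > ", fixed = TRUE)[[1]]
  }
  early_window <- if (length(tints) > 0) seq_len(max(min(tints) - 1, 0)) else 1:T_max
  late_window <- if (length(tints) > 0) {
    seq(min(max(tints) + 1, T_max), T_max)
  } else {
    integer(0)
  }

  long <- purrr::imap_dfr(curves, function(cv, nm) {
    dplyr::mutate(as_tibble(cv), strategy = nm, .before = 1)
  })
  structure(
    list(
      curves = long, pairwise = pairwise,
      early_ranking = modal_ranking(early_window),
      late_ranking = modal_ranking(late_window),
      early_window = range(early_window),
      late_window = if (length(late_window)) range(late_window) else integer(0),
      ranking_at = rank_at
    ),
    class = "strategy_comparison"
  )
}

#' @export
print.strategy_comparison <- function(x, ...) {
  cat("<strategy_comparison>\n")
  cat(
    "early ranking (t in [", paste(x$early_window, collapse = ", "), "]): ",
    paste(x$early_ranking, collapse = " > "), "\n",
    sep = ""
  )
  cat(
    "late ranking  (t in [", paste(x$late_window, collapse = ", "), "]): ",
    paste(x$late_ranking, collapse = " > "), "\n",
    sep = ""
  )
  print(x$pairwise, ...)
  invisible(x)
}

#' @describeIn compare_strategies Pairwise interlace/leader table.
#' @param x A `strategy_comparison`.
#' @param ... Unused.
#' @export
tidy.strategy_comparison <- function(x, ...) x$pairwise

#' @describeIn compare_strategies Overlaid CDF curves per strategy.
#' @param object A `strategy_comparison`.
#' @export
autoplot.strategy_comparison <- function(object, ...) {
  ggplot2::ggplot(
    object$curves,
    ggplot2::aes(.data$t, .data$cdf, colour = .data$strategy)
  ) +
    ggplot2::geom_step() +
    ggplot2::labs(
      x = "decision period t", y = expression(P[com](t)),
      title = "Goal-reaching CDF by strategy"
    ) +
    ggplot2::theme_minimal()
}

# all nonnegative integer vectors of length k summing to total
.compositions <- function(total, k) {
  if (k == 1) return(matrix(total, 1, 1))
  out <- lapply(0:total, function(first) {
    cbind(first, .compositions(total - first, k - 1), deparse.level = 0)
  })
  do.call(rbind, out)
}

#' Search for a strategy maximizing P_com at a target time
#'
#' The weight matrix has `g (g + 1) / 2` free entries, so beyond tiny games
#' the best strategy for a deadline cannot be solved in closed form; the
#' model's prescription is to evaluate trial weightings and keep the best.
#' Candidates are either a simplex grid over every stage's weights (small
#' games) or seeded Dirichlet(1) draws; each is scored by the probability
#' of having reached the goal within `objective_t` periods.
#'
#' @param game A [decision_game()].
#' @param objective_t The deadline `t` whose `P_com(t)` is maximized.
#' @param family `"grid"` (exhaustive simplex grid, games with `g <= 4`)
#'   or `"dirichlet_random"` (seeded random weightings, any size).
#' @param n_trials Candidate budget (grid resolution is chosen to stay
#'   within it; at least the coarsest grid is evaluated).
#' @param seed Seed for the random family; the result is deterministic
#'   given the seed.
#' @return A list with `strategy` (the best `decision_strategy`), `value`
#'   (its `P_com(objective_t)`) and `n_evaluated`.
#' @examples
#' search_strategy(standard_game(2), objective_t = 1, family = "grid")$value
#' @export
search_strategy <- function(game, objective_t,
                            family = c("grid", "dirichlet_random"),
                            n_trials = 500, seed = 1) {
  stopifnot(inherits(game, "decision_game"))
  family <- match.arg(family)
  if (!.is_count(objective_t) || objective_t != round(objective_t)) {
    abort("`objective_t` must be a positive integer.")
  }
  if (!.is_count(n_trials)) abort("`n_trials` must be at least 1.")
  g <- game$goal_stages
  k_at <- vapply(game$options_at, nrow, 1L) # options per stage
  free <- which(k_at > 1) # stages with a real choice (1-based index = stage+1)

  score <- function(weights) {
    A <- .compose_weights(game, weights)
    .cdf_vector(A, horizon = objective_t)[objective_t + 1]
  }
  base_weights <- lapply(seq_along(k_at), function(i) {
    if (k_at[i] == 0) numeric(0) else c(1, rep(0, k_at[i] - 1))
  })

  if (length(free) == 0) {
    w <- lapply(k_at, function(k) if (k == 0) numeric(0) else rep(1, k))
    best <- .new_strategy(game, "forced", w)
    return(list(
      strategy = best, value = score(w), n_evaluated = 1L
    ))
  }

  if (family == "grid") {
    if (g > 4) abort("Grid search is exhaustive; use dirichlet_random for g > 4.")
    # largest resolution whose full grid fits in n_trials
    den <- 1
    grid_size <- function(d) {
      prod(vapply(free, function(i) choose(d + k_at[i] - 1, k_at[i] - 1), 1))
    }
    while (grid_size(den + 1) <= n_trials) den <- den + 1
    per_stage <- lapply(free, function(i) .compositions(den, k_at[i]) / den)
    idx <- expand.grid(lapply(per_stage, function(m) seq_len(nrow(m))))
    cands <- lapply(seq_len(nrow(idx)), function(r) {
      w <- base_weights
      for (j in seq_along(free)) {
        w[[free[j]]] <- per_stage[[j]][idx[r, j], ]
      }
      w
    })
  } else {
    cands <- withr::with_seed(seed, {
      lapply(seq_len(n_trials), function(r) {
        w <- base_weights
        for (i in free) {
          x <- stats::rgamma(k_at[i], 1)
          w[[i]] <- x / sum(x)
        }
        w
      })
    })
  }

  values <- vapply(cands, score, 1)
  best <- which.max(values) # first maximum: deterministic tie-break
  list(
    strategy = .new_strategy(game, paste0("search_", family), cands[[best]]),
    value = values[best],
    n_evaluated = length(cands)
  )
}

# fix-route curve for a single option toward a goal; clamping makes the
# route well-defined even when u does not divide the goal
.single_option_curve <- function(u, p, goal, label = "opt", horizon = NULL,
                                 epsilon = 1e-9) {
  game <- decision_game(
    data.frame(label = label, u = u, p = p), goal,
    overshoot = "clamp"
  )
  w <- lapply(game$options_at, function(at) rep(1, nrow(at)))
  A <- transition_matrix(game, .new_strategy(game, paste0("fix(", label, ")"), w))
  curve_from_matrix(A, horizon = horizon, epsilon = epsilon)
}

#' Estimate the time window consistent with observed choices
#'
#' Given choice problems in which one option was chosen over another, and a
#' candidate goal, this finds the integer times `t` at which every chosen
#' option's goal-reaching CDF strictly exceeds its rejected alternative's.
#' A non-empty window says: the observed choices are exactly what a
#' `P_com(t)`-maximizer with that goal and a deadline in the window would
#' do — a way to read a goal and an urgency off someone's decisions.
#'
#' @param choice_problems Data frame with one row per problem and columns
#'   `chosen_u`, `chosen_p`, `rejected_u`, `rejected_p` (monetary `u`).
#' @param candidate_goal Monetary goal to test.
#' @param epsilon Tail mass for the per-curve auto-horizon.
#' @param tol Strictness tolerance on CDF differences.
#' @return A tibble of maximal integer intervals (`start`, `end`) on which
#'   all choices are simultaneously explained; zero rows if the goal
#'   explains no window. Per-problem windows are in the `per_problem`
#'   attribute.
#' @examples
#' kt <- data.frame(
#'   chosen_u = c(4000, 3000), chosen_p = c(0.2, 1),
#'   rejected_u = c(3000, 4000), rejected_p = c(0.25, 0.8)
#' )
#' estimate_goal_window(kt, 12000)
#' @export
estimate_goal_window <- function(choice_problems, candidate_goal,
                                 epsilon = 1e-9, tol = .TOL_TIE) {
  need <- c("chosen_u", "chosen_p", "rejected_u", "rejected_p")
  if (!is.data.frame(choice_problems) || !all(need %in% names(choice_problems))) {
    abort(paste0(
      "`choice_problems` needs columns ",
      paste(need, collapse = ", "), "."
    ))
  }
  cp <- as_tibble(choice_problems)
  curves <- purrr::pmap(cp[need], function(chosen_u, chosen_p, rejected_u,
                                           rejected_p) {
    list(
      chosen = .single_option_curve(chosen_u, chosen_p, candidate_goal,
        epsilon = epsilon
      ),
      rejected = .single_option_curve(rejected_u, rejected_p, candidate_goal,
        epsilon = epsilon
      )
    )
  })
  T_max <- max(vapply(
    curves,
    function(pr) max(nrow(pr$chosen), nrow(pr$rejected)), 1
  )) - 1
  ok <- rep(TRUE, T_max + 1)
  per <- vector("list", length(curves))
  for (i in seq_along(curves)) {
    ext <- function(cv) {
      if (nrow(cv) - 1 < T_max) {
        curve_from_matrix(attr(cv, "matrix"), horizon = T_max)
      } else {
        cv
      }
    }
    a <- ext(curves[[i]]$chosen)$cdf
    b <- ext(curves[[i]]$rejected)$cdf
    win <- a - b > tol
    per[[i]] <- .runs_to_intervals(win)
    ok <- ok & win
  }
  out <- .runs_to_intervals(ok)
  attr(out, "per_problem") <- per
  attr(out, "candidate_goal") <- candidate_goal
  out
}

# logical vector over t = 0..T -> tibble of maximal TRUE intervals
.runs_to_intervals <- function(flag) {
  t <- seq_along(flag) - 1
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  tibble(
    start = t[starts[keep]],
    end = t[ends[keep]]
  )
}

#' Lower bound on inconsistent responders
#'
#' If a fraction `frac_first` of subjects gave one answer on the first
#' problem and `frac_second` gave a particular answer on the second, then
#' at least `max(0, frac_first + frac_second - 1)` of the common subjects
#' gave both — the Bonferroni/Frechet overlap bound. Applied to the classic
#' paired lottery questions (65% risky on the first, 80% safe on the
#' second) it says at least 45% of subjects answered "inconsistently"
#' under the expected-utility reading.
#'
#' @param frac_first,frac_second Fractions in `[0, 1]`.
#' @return The lower bound, in `[0, 1]`.
#' @examples
#' inconsistency_lower_bound(0.65, 0.80)
#' @export
inconsistency_lower_bound <- function(frac_first, frac_second) {
  if (!is.numeric(frac_first) || !is.numeric(frac_second) ||
    any(frac_first < 0 | frac_first > 1) ||
    any(frac_second < 0 | frac_second > 1)) {
    abort("Fractions must lie in [0, 1].")
  }
  pmax(0, frac_first + frac_second - 1)
}
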