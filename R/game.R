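# Game construction: payoff table -> stage network -> game matrix Q.

# Greatest common divisor of positive reals that are commensurable
# (integer multiples of a common unit). Euclid with a relative tolerance;
# irrational ratios never terminate cleanly and are rejected upstream by
# the divisibility check in decision_game().
.gcd2 <- function(a, b, tol = 1e-9) {
  while (b > tol * a) {
    r <- a %% b
    if (r > b - tol * a) r <- 0
    a2 <- b
    b <- r
    a <- a2
  }
  a
}

.gcd <- function(x) Reduce(.gcd2, x)

.is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x > 0

#' Build a decision game from a payoff table
#'
#' A decision game is a stage network: a decision maker holds a goal worth
#' `goal` in monetary units and repeatedly picks one option from the payoff
#' table. An option `(u, p)` pays `u` with probability `p` and nothing
#' otherwise, so a win advances the decision maker `u / stage_unit` stages
#' toward the goal. The stage unit is the greatest common divisor of all
#' option utilities and the goal, so every position on the way to the goal
#' is an integer stage index.
#'
#' In *Approaching* mode stages are labelled by distance: `S_k` means `k`
#' stages remain, `S_0` is the goal and the walk starts at `S_g`. In
#' *Growing* mode stages count accumulated winnings: the walk starts at
#' `S_0` and absorbs at `S_g` (or beyond). The two constructions are
#' isomorphic under the relabelling `S_j <-> S_{g - j}`.
#'
#' @param options A data frame with columns `u` (monetary utility, positive),
#'   `p` (win probability in (0, 1]) and optionally `label`.
#' @param goal Positive monetary goal.
#' @param mode `"approaching"` (default) or `"growing"`.
#' @param tau Seconds per decision period; metadata only, used to annotate
#'   real time `t * tau` in outputs.
#' @param overshoot What to do when an option's utility exceeds the stages
#'   remaining: `"clamp"` (default) treats any move past the goal as arrival
#'   at the goal; `"strict"` makes the option unavailable at that stage.
#' @param stage_unit Monetary value of one stage. By default the greatest
#'   common divisor of all utilities and the goal (the coarsest faithful
#'   lattice); pass a smaller exact divisor (e.g. `1`) to work on a finer
#'   lattice — all curves and hitting times are invariant to this choice.
#' @return A `decision_game` object: a list with `goal_stages` (g),
#'   `stage_unit`, `mode`, `tau`, `overshoot`, an `options` tibble in stage
#'   units, and `options_at`, the per-stage availability table.
#' @examples
#' g24 <- decision_game(
#'   data.frame(label = c("A", "C"), u = c(6, 4), p = c(1 / 3, 0.5)),
#'   goal = 24
#' )
#' g24$goal_stages
#' @seealso [standard_game()], [game_matrix()], [goal_curve()]
#' @export
decision_game <- function(options, goal, mode = c("approaching", "growing"),
                          tau = 1, overshoot = c("clamp", "strict"),
                          stage_unit = NULL) {
  mode <- match.arg(mode)
  overshoot <- match.arg(overshoot)
  if (!is.data.frame(options) || !all(c("u", "p") %in% names(options))) {
    abort("`options` must be a data frame with columns `u` and `p`.")
  }
  options <- as_tibble(options)
  if (!"label" %in% names(options)) {
    options$label <- paste0("opt", seq_len(nrow(options)))
  }
  if (nrow(options) == 0) abort("At least one option is required.")
  if (any(!is.finite(options$u)) || any(options$u <= 0)) {
    abort("Option utilities must be positive and finite.")
  }
  if (any(!is.finite(options$p)) || any(options$p <= 0) || any(options$p > 1)) {
    abort("Option probabilities must lie in (0, 1].")
  }
  if (!.is_count(goal)) abort("`goal` must be a single positive number.")
  if (!.is_count(tau)) abort("`tau` must be a single positive number.")

  unit <- stage_unit %||% .gcd(c(options$u, goal))
  if (!.is_count(unit)) abort("`stage_unit` must be a single positive number.")
  stages_raw <- c(options$u, goal) / unit
  off <- which(abs(stages_raw - round(stages_raw)) > 1e-6)
  # a "common unit" thousands of times finer than the goal means the values
  # share no real one (irrational or near-irrational ratios)
  if (length(off) > 0 || goal / unit > 1e5) {
    bad <- if (length(off) > 0 && off[1] <= nrow(options)) {
      options$label[off[1]]
    } else {
      "goal"
    }
    abort(paste0(
      "Utilities and goal are not commensurable: `", bad,
      "` is not an integer multiple of a reasonable stage unit."
    ))
  }

  opts <- tibble(
    label = as.character(options$label),
    u = as.integer(round(options$u / unit)),
    p = as.numeric(options$p),
    monetary_u = as.numeric(options$u)
  )
  if (anyDuplicated(opts$u) > 0) {
    abort("Two options share the same utility; links would be ambiguous.")
  }

  game <- structure(
    list(
      goal_stages = as.integer(round(goal / unit)),
      stage_unit = unit,
      monetary_goal = as.numeric(goal),
      mode = mode,
      tau = as.numeric(tau),
      overshoot = overshoot,
      options = opts,
      standard = FALSE
    ),
    class = "decision_game"
  )
  game$options_at <- .options_at(game)
  game
}

# Per-stage availability: list indexed by stage 0..g (element k + 1 is the
# tibble of options usable at S_k, with the destination stage resolved under
# the overshoot policy). Absorbing stages get an empty table.
.options_at <- function(game) {
  g <- game$goal_stages
  opts <- game$options
  lapply(0:g, function(k) {
    if (game$mode == "approaching") {
      if (k == 0) return(opts[0, c("label", "u", "p")])
      avail <- if (game$overshoot == "strict") opts$u <= k else rep(TRUE, nrow(opts))
      out <- opts[avail, c("label", "u", "p")]
      out$dest <- pmax(k - out$u, 0L)
    } else {
      if (k >= g) return(opts[0, c("label", "u", "p")])
      avail <- if (game$overshoot == "strict") opts$u <= g - k else rep(TRUE, nrow(opts))
      out <- opts[avail, c("label", "u", "p")]
      out$dest <- pmin(k + out$u, g)
    }
    out
  })
}

#' Standard game: every option has expected utility one
#'
#' The standard game of goal `g` offers, at stage `S_k`, the options
#' `(i, 1/i)` for `i = 1..k`: win `i` stages with probability `1/i`. Every
#' option has expected utility exactly 1, which removes any expected-utility
#' privilege between options and isolates the effect of strategy. It is the
#' setting on which the named strategies (`min_k`, `max_k`, `risky`,
#' `random`, `safe`) are defined.
#'
#' @param g Positive integer goal, in stages.
#' @return A `decision_game` in Approaching mode whose option set at `S_k`
#'   is `(i, 1/i)`, `i = 1..k`.
#' @examples
#' standard_game(10)
#' @export
standard_game <- function(g) {
  if (!.is_count(g) || g != round(g)) abort("`g` must be a positive integer.")
  g <- as.integer(g)
  opts <- tibble(
    label = paste0("u", 1:g),
    u = 1:g,
    p = 1 / (1:g),
    monetary_u = as.numeric(1:g)
  )
  game <- structure(
    list(
      goal_stages = g,
      stage_unit = 1,
      monetary_goal = as.numeric(g),
      mode = "approaching",
      tau = 1,
      overshoot = "strict",
      options = opts,
      standard = TRUE
    ),
    class = "decision_game"
  )
  # strict availability u <= k reproduces the k options of S_k exactly
  game$options_at <- .options_at(game)
  game
}

#' Game matrix Q of a decision game
#'
#' The game matrix holds the per-link win probabilities implied by the
#' payoff table alone, independent of any strategy: `q[i, j] = p_m` when the
#' option of utility `m = i - j` (Approaching; `m = j - i` in Growing mode)
#' is available at `S_i`. Under the clamping overshoot policy two distinct
#' options can share a destination, which has no single-link representation;
#' such games are rejected here (use [transition_matrix()], which composes
#' at the option level).
#'
#' @param game A [decision_game()].
#' @return A `(g+1) x (g+1)` numeric matrix, lower-triangular in Approaching
#'   mode, upper-triangular in Growing mode.
#' @examples
#' game_matrix(standard_game(3))
#' @export
game_matrix <- function(game) {
  stopifnot(inherits(game, "decision_game"))
  g <- game$goal_stages
  Q <- matrix(0, g + 1, g + 1)
  for (k in 0:g) {
    at <- game$options_at[[k + 1]]
    if (nrow(at) == 0) next
    if (anyDuplicated(at$dest) > 0) {
      abort(paste0(
        "Ambiguous link: two options at stage ", k,
        " lead to the same stage (overshoot clamping); ",
        "use transition_matrix() or overshoot = \"strict\"."
      ))
    }
    Q[k + 1, at$dest + 1] <- at$p
  }
  dimnames(Q) <- list(paste0("S", 0:g), paste0("S", 0:g))
  Q
}

#' @export
print.decision_game <- function(x, ...) {
  cat(sprintf(
    "<decision_game> %s mode, goal %s (%d stages of %s), tau = %s s/period\n",
    x$mode, format(x$monetary_goal), x$goal_stages, format(x$stage_unit),
    format(x$tau)
  ))
  if (x$standard) {
    cat(sprintf("standard game: options (i, 1/i), i = 1..%d\n", x$goal_stages))
  } else {
    cat(sprintf("%d option(s), overshoot policy: %s\n", nrow(x$options), x$overshoot))
    print(x$options, ...)
  }
  invisible(x)
}

# resolve a user-supplied utility (monetary, falling back to stage units)
# to a row of game$options
.resolve_option <- function(game, utility) {
  hit <- which(abs(game$options$monetary_u - utility) < 1e-9)
  if (length(hit) == 0) hit <- which(game$options$u == utility)
  if (length(hit) != 1) {
    abort(paste0("No option of utility ", format(utility), " in this game."))
  }
  hit
}

# signature used to check that curves/ensembles come from the same game
.game_signature <- function(game) {
  paste(
    game$mode, game$goal_stages, format(game$stage_unit), game$overshoot,
    paste(game$options$u, collapse = ","),
    paste(signif(game$options$p, 12), collapse = ","),
    sep = "|"
  )
}

#' @describeIn decision_game Tidy view of the payoff table: one row per
#'   option with stage-unit utility, probability and expected utility.
#' @param x A `decision_game`.
#' @param ... Unused.
#' @export
tidy.decision_game <- function(x, ...) {
  dplyr::mutate(
    x$options,
    expected_utility = .data$u * .data$p
  )
}
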