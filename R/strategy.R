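# Strategy matrices W: how a decision maker weights the available options.

.new_strategy <- function(game, name, weights) {
  # weights: list indexed by stage 0..g, numeric vector parallel to the
  # rows of game$options_at[[k + 1]]
  rows <- vector("list", game$goal_stages + 1)
  for (k in 0:game$goal_stages) {
    at <- game$options_at[[k + 1]]
    w <- weights[[k + 1]]
    if (nrow(at) == 0) next
    if (any(w < 0)) abort(paste0("Negative weight at stage ", k, "."))
    s <- sum(w)
    if (abs(s - 1) > 1e-12) {
      abort(paste0(
        "Weights at stage ", k, " sum to ", format(s), ", not 1 ",
        "(set renormalize = TRUE to rescale)."
      ))
    }
    rows[[k + 1]] <- dplyr::mutate(at, stage = k, weight = w)
  }
  structure(
    list(
      name = name,
      weights = weights,
      table = dplyr::bind_rows(rows)[, c(
        "stage", "label", "u", "p", "dest",
        "weight"
      )],
      game_signature = .game_signature(game),
      goal_stages = game$goal_stages,
      mode = game$mode
    ),
    class = "decision_strategy"
  )
}

#' Named strategies of the decision game
#'
#' Builds the strategy matrix W for one of the canonical policies. At stage
#' `S_i` of the standard game the options are `(k, 1/k)`, `k = 1..i`, and
#' the weight put on option `k` is:
#'
#' * `fix` — all weight on one chosen option `(m, p_m)` at every stage; the
#'   route visits only stages `g - n m`, so `m` must divide `g`.
#' * `min_k` — all weight on the surest option `(1, 1)`: advance one stage
#'   per period, reaching the goal at exactly `t = g`.
#' * `max_k` — all weight on the riskiest option `(g, 1/g)`: jump straight
#'   to the goal or stay put.
#' * `risky` — weight proportional to utility: `w_k = 2k / (i (i + 1))`.
#' * `random` — uniform weight `1 / i`.
#' * `safe` — weight proportional to probability: `w_k = (1/k) / H_i` with
#'   `H_i` the i-th harmonic number.
#'
#' `fix` works on any game offering the chosen option; the other named
#' weightings are defined by the standard game's option structure and error
#' elsewhere.
#'
#' @param game A [decision_game()].
#' @param name One of `"fix"`, `"min_k"`, `"max_k"`, `"risky"`, `"random"`,
#'   `"safe"`.
#' @param fix_utility For `fix`: the utility of the option to repeat, in
#'   the payoff table's monetary units (stage units also accepted). Must
#'   name an available option whose stage utility divides the goal.
#' @return A `decision_strategy` object; `as.matrix()` gives the
#'   `(g+1) x (g+1)` weight matrix W with rows summing to 1.
#' @examples
#' sg <- standard_game(10)
#' named_strategy(sg, "risky")
#' named_strategy(decision_game(data.frame(u = 6, p = 1 / 3), 24),
#'   "fix",
#'   fix_utility = 6
#' )
#' @export
named_strategy <- function(game, name = c(
                             "fix", "min_k", "max_k", "risky",
                             "random", "safe"
                           ),
                           fix_utility = NULL) {
  stopifnot(inherits(game, "decision_game"))
  name <- match.arg(name)
  g <- game$goal_stages

  if (name == "fix") {
    if (is.null(fix_utility)) abort("`fix` requires `fix_utility`.")
    m <- game$options$u[.resolve_option(game, fix_utility)]
    if (g %% m != 0) {
      abort(paste0(
        "Route undefined: fix utility ", m, " does not divide the goal of ",
        g, " stages."
      ))
    }
    weights <- lapply(0:g, function(k) {
      at <- game$options_at[[k + 1]]
      if (nrow(at) == 0) return(numeric(0))
      if (m %in% at$u) return(as.numeric(at$u == m))
      # the fix route from S_g only visits multiples of m, so stages
      # without the option are unreachable; give them a harmless default
      if (k %% m == 0 && k >= m) {
        abort(paste0("Fix option (", m, ") unavailable at stage ", k, "."))
      }
      as.numeric(seq_len(nrow(at)) == 1)
    })
    return(.new_strategy(game, paste0("fix(", m, ")"), weights))
  }

  if (!game$standard) {
    abort(paste0(
      "Strategy `", name, "` is defined on the standard game's option ",
      "structure; use `fix` or custom_strategy() on this game."
    ))
  }
  weights <- lapply(0:g, function(i) {
    at <- game$options_at[[i + 1]]
    if (nrow(at) == 0) return(numeric(0))
    k <- at$u # 1..i in the standard game
    switch(name,
      min_k  = as.numeric(k == 1),
      max_k  = as.numeric(k == i),
      risky  = 2 * k / (i * (i + 1)),
      random = rep(1 / i, length(k)),
      safe   = (1 / k) / sum(1 / k)
    )
  })
  .new_strategy(game, name, weights)
}

#' Arbitrary strategy weights
#'
#' Builds a strategy matrix from explicit per-stage weights, for exploring
#' policies beyond the named ones. Weights are given as a data frame with
#' columns `stage`, `u` and `weight` (one row per stage/option pair); stages
#' not mentioned put all weight on... nothing — every stage with at least
#' one available option must have its weights specified.
#'
#' @param game A [decision_game()].
#' @param weights Data frame with columns `stage`, `u`, `weight`, or a named
#'   list of named lists (`weights[["3"]][["2"]]` = weight on the utility-2
#'   option at stage 3), as produced by strategy JSON files.
#' @param renormalize If `TRUE`, each stage's weights are rescaled to sum
#'   to 1; if `FALSE` (default) a row sum away from 1 is an error.
#' @return A `decision_strategy`.
#' @examples
#' sg <- standard_game(2)
#' custom_strategy(sg, data.frame(
#'   stage = c(1, 2, 2), u = c(1, 1, 2),
#'   weight = c(1, 0.5, 0.5)
#' ))
#' @export
custom_strategy <- function(game, weights, renormalize = FALSE) {
  stopifnot(inherits(game, "decision_game"))
  g <- game$goal_stages
  if (is.data.frame(weights)) {
    wdf <- as_tibble(weights)
    if (!all(c("stage", "u", "weight") %in% names(wdf))) {
      abort("`weights` needs columns `stage`, `u`, `weight`.")
    }
  } else if (is.list(weights)) {
    wdf <- purrr::imap_dfr(weights, function(wk, stage) {
      tibble(
        stage = as.integer(stage),
        u = as.integer(names(wk)),
        weight = as.numeric(unlist(wk))
      )
    })
  } else {
    abort("`weights` must be a data frame or a named list.")
  }
  if (any(wdf$weight < 0)) abort("Weights must be nonnegative.")

  wl <- lapply(0:g, function(k) {
    at <- game$options_at[[k + 1]]
    if (nrow(at) == 0) return(numeric(0))
    here <- wdf[wdf$stage == k, ]
    bad <- setdiff(here$u, at$u)
    if (length(bad) > 0) {
      abort(paste0(
        "Weight on unavailable option (utility ", bad[1],
        ") at stage ", k, "."
      ))
    }
    w <- setNames(rep(0, nrow(at)), at$u)
    w[as.character(here$u)] <- here$weight
    if (renormalize) {
      s <- sum(w)
      if (s <= 0) abort(paste0("No positive weight at stage ", k, "."))
      w <- w / s
    }
    unname(w)
  })
  .new_strategy(game, "custom", wl)
}

#' @export
as.matrix.decision_strategy <- function(x, ...) {
  g <- x$goal_stages
  W <- matrix(0, g + 1, g + 1)
  # columns are destinations; without overshoot dest = i - u, i.e. the
  # textbook b[i, j] = weight on the option of utility i - j
  tb <- x$table
  for (r in seq_len(nrow(tb))) {
    W[tb$stage[r] + 1, tb$dest[r] + 1] <- W[tb$stage[r] + 1, tb$dest[r] + 1] +
      tb$weight[r]
  }
  dimnames(W) <- list(paste0("S", 0:g), paste0("S", 0:g))
  W
}

#' @describeIn named_strategy One row per stage/option with its weight.
#' @param x A `decision_strategy`.
#' @param ... Unused.
#' @export
tidy.decision_strategy <- function(x, ...) {
  x$table
}

#' @export
print.decision_strategy <- function(x, ...) {
  cat(sprintf(
    "<decision_strategy> %s on a %d-stage %s-mode game\n",
    x$name, x$goal_stages, x$mode
  ))
  invisible(x)
}
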