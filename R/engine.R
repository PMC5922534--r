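# Transition matrix A = Q o W + D, iteration, goal-reaching curves, and
# hitting-time moments.

.new_transition <- function(A, start, absorb, tau = 1, strategy = "?",
                            signature = NA_character_, goal = NA_real_) {
  stopifnot(nrow(A) == ncol(A))
  rs <- rowSums(A)
  if (any(abs(rs - 1) > .TOL_ROW)) {
    abort(paste0(
      "Internal consistency error: transition row ",
      which.max(abs(rs - 1)) - 1, " sums to ",
      format(rs[which.max(abs(rs - 1))]), " (malformed W or Q)."
    ))
  }
  structure(A,
    start = start, absorb = absorb, tau = tau,
    strategy = strategy, signature = signature, goal = goal,
    class = c("transition_matrix", class(A))
  )
}

#' Transition matrix of a game under a strategy
#'
#' Composes the row-stochastic transition matrix `A` of the decision walk:
#' for each option `(u, p)` carrying weight `w` at stage `S_i`, the move to
#' its destination contributes `w * p`, and `w * (1 - p)` joins the staying
#' probability on the diagonal. The goal row is absorbing. Composition is
#' done option-by-option, so it remains valid when overshoot clamping sends
#' two options to the same destination; when the game matrix Q is
#' well-formed the result equals the Hadamard composition
#' [compose_transition()] exactly.
#'
#' @param game A [decision_game()].
#' @param strategy A `decision_strategy` built on the same game.
#' @return A `(g+1) x (g+1)` transition matrix (class `transition_matrix`)
#'   carrying the start and absorbing stage indices as attributes.
#' @examples
#' sg <- standard_game(3)
#' transition_matrix(sg, named_strategy(sg, "random"))
#' @export
transition_matrix <- function(game, strategy) {
  stopifnot(inherits(game, "decision_game"), inherits(strategy, "decision_strategy"))
  if (!identical(strategy$game_signature, .game_signature(game))) {
    abort("Strategy was built for a different game.")
  }
  A <- .compose_weights(game, strategy$weights)
  attr(A, "strategy") <- strategy$name
  A
}

# option-level composition from raw per-stage weight vectors (the fast path
# shared by transition_matrix() and the strategy search)
.compose_weights <- function(game, weights) {
  g <- game$goal_stages
  absorb <- if (game$mode == "approaching") 0L else g
  start <- if (game$mode == "approaching") g else 0L
  A <- matrix(0, g + 1, g + 1)
  for (k in 0:g) {
    at <- game$options_at[[k + 1]]
    w <- weights[[k + 1]]
    if (nrow(at) == 0) {
      A[k + 1, k + 1] <- 1 # absorbing goal row (or dead stage, strict mode)
      next
    }
    for (r in seq_len(nrow(at))) {
      A[k + 1, at$dest[r] + 1] <- A[k + 1, at$dest[r] + 1] + w[r] * at$p[r]
    }
    A[k + 1, k + 1] <- A[k + 1, k + 1] + sum(w * (1 - at$p))
  }
  dimnames(A) <- list(paste0("S", 0:g), paste0("S", 0:g))
  .new_transition(A,
    start = start, absorb = absorb, tau = game$tau,
    signature = .game_signature(game), goal = game$monetary_goal
  )
}

#' Hadamard composition A = Q o W + D
#'
#' The matrix-level route to the transition matrix: off-diagonal entries are
#' the elementwise products `q[i,j] * b[i,j]`, and the diagonal `D` holds
#' the staying mass `sum_m w_m (1 - p_m)`, recovered as one minus the row's
#' outgoing mass. Requires a well-formed Q (one link per destination); the
#' option-level [transition_matrix()] is the general constructor.
#'
#' @param Q Game matrix from [game_matrix()].
#' @param W Weight matrix, e.g. `as.matrix()` of a `decision_strategy`.
#' @param absorb Index (0-based) of the absorbing goal stage; 0 for
#'   Approaching mode, `g` for Growing mode.
#' @return A `transition_matrix`.
#' @examples
#' sg <- standard_game(3)
#' compose_transition(game_matrix(sg), as.matrix(named_strategy(sg, "safe")))
#' @export
compose_transition <- function(Q, W, absorb = 0L) {
  stopifnot(is.matrix(Q), is.matrix(W), all(dim(Q) == dim(W)))
  n <- nrow(Q)
  A <- Q * W
  diag(A) <- 0
  out <- rowSums(W)
  diag(A) <- ifelse(out > 0, pmax(out - rowSums(A), 0), 1)
  A[absorb + 1, ] <- 0
  A[absorb + 1, absorb + 1] <- 1
  dimnames(A) <- dimnames(Q)
  g <- n - 1L
  .new_transition(A,
    start = if (absorb == 0L) g else 0L, absorb = as.integer(absorb)
  )
}

#' Reduced band chain of a fix strategy
#'
#' Under the fix strategy on option `(m, p)` only the stages `S_{g - n m}`
#' are ever visited, so the `(g+1)`-stage lattice collapses to a chain of
#' `g/m + 1` nodes whose transition matrix is a band matrix: `p` on the
#' first sub-diagonal, `1 - p` on the diagonal, absorbing at the goal. Its
#' curves and hitting times are identical to the full-lattice composition.
#'
#' @param game A [decision_game()] offering an option of utility
#'   `fix_utility`.
#' @param fix_utility Stage-unit utility `m` of the repeated option; must
#'   divide the goal.
#' @return A `(g/m + 1) x (g/m + 1)` `transition_matrix`; node `i` of the
#'   chain is the stage `m * i` stages from the goal.
#' @examples
#' g24 <- decision_game(data.frame(label = "A", u = 6, p = 1 / 3), 24)
#' reduce_fix_chain(g24, 6)
#' @export
reduce_fix_chain <- function(game, fix_utility) {
  stopifnot(inherits(game, "decision_game"))
  row <- .resolve_option(game, fix_utility)
  m <- game$options$u[row]
  g <- game$goal_stages
  if (g %% m != 0) {
    abort(paste0("Route undefined: ", m, " does not divide ", g, "."))
  }
  p <- game$options$p[row]
  n <- g %/% m
  A <- matrix(0, n + 1, n + 1)
  A[1, 1] <- 1
  for (i in 1:n) {
    A[i + 1, i] <- p
    A[i + 1, i + 1] <- 1 - p
  }
  dimnames(A) <- list(paste0("S", m * (0:n)), paste0("S", m * (0:n)))
  .new_transition(A,
    start = n, absorb = 0L, tau = game$tau,
    strategy = paste0("fix(", m, ")"), signature = .game_signature(game),
    goal = game$monetary_goal
  )
}

#' Iterate the state vector R(t+1) = R(t) A
#'
#' Repeated vector-matrix products of the occupancy distribution over
#' stages; entry `i` of `R(t)` is the probability of being at stage `i`
#' after `t` decision periods.
#'
#' @param A A `transition_matrix` (or plain stochastic matrix).
#' @param horizon Number of periods to iterate (>= 1).
#' @param initial Optional initial distribution; defaults to point mass at
#'   the start stage.
#' @return A `(horizon + 1) x (g + 1)` matrix whose row `t + 1` is `R(t)`.
#' @examples
#' sg <- standard_game(3)
#' iterate_states(transition_matrix(sg, named_strategy(sg, "min_k")), 3)
#' @export
iterate_states <- function(A, horizon, initial = NULL) {
  if (!.is_count(horizon) || horizon != round(horizon)) {
    abort("`horizon` must be a positive integer.")
  }
  n <- nrow(A)
  if (is.null(initial)) {
    start <- attr(A, "start") %||% (n - 1L)
    initial <- numeric(n)
    initial[start + 1] <- 1
  }
  stopifnot(length(initial) == n, abs(sum(initial) - 1) < .TOL_ROW)
  out <- matrix(0, horizon + 1, n)
  out[1, ] <- initial
  r <- initial
  for (t in seq_len(horizon)) {
    r <- as.numeric(r %*% A)
    out[t + 1, ] <- r
  }
  rownames(out) <- paste0("t", 0:horizon)
  colnames(out) <- colnames(A)
  out
}

# core CDF computation with auto-horizon (tail < epsilon) and a hard cap
.cdf_vector <- function(A, horizon = NULL, epsilon = 1e-9,
                        max_horizon = 1e6) {
  n <- nrow(A)
  absorb <- attr(A, "absorb") %||% 0L
  start <- attr(A, "start") %||% (n - 1L)
  r <- numeric(n)
  r[start + 1] <- 1
  cdf <- r[absorb + 1]
  t <- 0
  limit <- horizon %||% max_horizon
  while (t < limit) {
    r <- as.numeric(r %*% A)
    t <- t + 1
    cdf <- c(cdf, r[absorb + 1])
    if (is.null(horizon) && 1 - cdf[t + 1] < epsilon) break
  }
  if (is.null(horizon) && 1 - cdf[length(cdf)] >= epsilon) {
    abort(paste0(
      "Auto-horizon failed: tail mass still ",
      format(1 - cdf[length(cdf)]), " after ", max_horizon, " periods."
    ))
  }
  cdf
}

#' Goal-reaching probability curves
#'
#' The central quantity of the model: `P_com(t)`, the probability of having
#' reached the goal within `t` decision periods, obtained by iterating the
#' composed transition matrix from the start stage and reading the mass on
#' the goal. The increments give the first-passage PMF
#' `P(t) = P_com(t) - P_com(t - 1)`.
#'
#' @param game A [decision_game()].
#' @param strategy A `decision_strategy`, or the name of a named strategy
#'   (passed to [named_strategy()]).
#' @param horizon Number of periods; `NULL` (default) extends until the
#'   unabsorbed tail falls below `epsilon`.
#' @param epsilon Tail mass at which the auto-horizon stops.
#' @param fix_utility Passed through when `strategy` is `"fix"`.
#' @return A `goal_curve`: a tibble with columns `t`, `cdf`, `pmf` and
#'   `real_time` (`t * tau`), carrying the transition matrix as an
#'   attribute. [glance()] reports the mean hitting time; [autoplot()]
#'   draws both curves.
#' @examples
#' glance(goal_curve(standard_game(10), "risky"))
#' @export
goal_curve <- function(game, strategy, horizon = NULL, epsilon = 1e-9,
                       fix_utility = NULL) {
  stopifnot(inherits(game, "decision_game"))
  if (is.character(strategy)) {
    strategy <- named_strategy(game, strategy, fix_utility = fix_utility)
  }
  A <- transition_matrix(game, strategy)
  curve_from_matrix(A, horizon = horizon, epsilon = epsilon)
}

#' @rdname goal_curve
#' @param A A `transition_matrix`, e.g. from [reduce_fix_chain()].
#' @export
curve_from_matrix <- function(A, horizon = NULL, epsilon = 1e-9) {
  cdf <- .cdf_vector(A, horizon = horizon, epsilon = epsilon)
  tau <- attr(A, "tau") %||% 1
  t <- seq_along(cdf) - 1
  out <- tibble(
    t = t,
    cdf = cdf,
    pmf = c(cdf[1], diff(cdf)),
    real_time = t * tau
  )
  structure(out,
    class = c("goal_curve", class(out)),
    strategy = attr(A, "strategy") %||% "?",
    signature = attr(A, "signature"),
    goal = attr(A, "goal") %||% NA_real_,
    matrix = A, tau = tau
  )
}

#' Mean time to reach the goal
#'
#' Expected number of decision periods until absorption at the goal,
#' computed exactly from the fundamental-matrix relation: with `T` the
#' transient block of `A`, the expected hitting times solve
#' `(I - T) n = 1`. A truncated-sum estimate (`sum_t t * P(t)`) is
#' available as a cross-check.
#'
#' On a standard game every option has expected progress `1` stage per
#' period, so every strategy's mean hitting time equals the goal `g`
#' exactly (Wald's identity); the curves differ only in spread.
#'
#' @param A A `transition_matrix`, or a [decision_game()] (then `strategy`
#'   is required).
#' @param strategy Strategy (object or name) when `A` is a game.
#' @param method `"solve"` (exact linear solve, default) or `"truncated"`
#'   (sum the PMF out to tail mass 1e-12).
#' @param ... Passed to [named_strategy()] when `strategy` is a name.
#' @return The expected number of periods (a positive scalar).
#' @examples
#' mean_hitting_time(standard_game(10), "safe")
#' @export
mean_hitting_time <- function(A, strategy = NULL,
                              method = c("solve", "truncated"), ...) {
  method <- match.arg(method)
  if (inherits(A, "decision_game")) {
    if (is.character(strategy)) strategy <- named_strategy(A, strategy, ...)
    A <- transition_matrix(A, strategy)
  }
  n <- nrow(A)
  start <- attr(A, "start") %||% (n - 1L)
  absorb <- attr(A, "absorb") %||% 0L

  # states reachable from the start through positive-probability moves
  reach <- rep(FALSE, n)
  frontier <- start + 1L
  reach[frontier] <- TRUE
  while (length(frontier) > 0) {
    nxt <- which(colSums(A[frontier, , drop = FALSE] > 0) > 0)
    nxt <- nxt[!reach[nxt]]
    reach[nxt] <- TRUE
    frontier <- nxt
  }
  if (!reach[absorb + 1]) {
    abort("Non-absorbing chain: the goal is unreachable from the start stage.")
  }
  trans <- setdiff(which(reach), absorb + 1L)
  dead <- trans[abs(A[cbind(trans, trans)] - 1) < .TOL_ROW]
  if (length(dead) > 0) {
    abort(paste0(
      "Non-absorbing chain: stage index ", dead[1] - 1,
      " has no outflow toward the goal."
    ))
  }

  if (method == "truncated") {
    cdf <- .cdf_vector(A, epsilon = 1e-12)
    return(sum(seq_along(cdf[-1]) * diff(cdf)))
  }
  Tm <- A[trans, trans, drop = FALSE]
  nvec <- solve(diag(length(trans)) - Tm, rep(1, length(trans)))
  unname(nvec[match(start + 1L, trans)])
}

#' @describeIn goal_curve One-row summary: strategy, horizon, final CDF,
#'   mean hitting time (in periods and real time).
#' @param x A `goal_curve`.
#' @param ... Unused.
#' @export
glance.goal_curve <- function(x, ...) {
  A <- attr(x, "matrix")
  mht <- mean_hitting_time(A)
  tibble(
    strategy = attr(x, "strategy"),
    horizon = max(x$t),
    cdf_final = x$cdf[nrow(x)],
    mean_hitting_time = mht,
    tau = attr(x, "tau"),
    mean_real_time = mht * attr(x, "tau")
  )
}

#' @describeIn goal_curve CDF and PMF panels against decision period.
#' @param object A `goal_curve`.
#' @export
autoplot.goal_curve <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object)[, c("t", "cdf", "pmf")],
    c("cdf", "pmf"),
    names_to = "curve", values_to = "probability"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$t, .data$probability)) +
    ggplot2::geom_step(ggplot2::aes(colour = .data$curve)) +
    ggplot2::facet_wrap(~curve, ncol = 1, scales = "free_y") +
    ggplot2::labs(
      x = "decision period t", y = NULL,
      title = paste0("Goal-reaching curves: ", attr(object, "strategy"))
    ) +
    ggplot2::theme_minimal()
}
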