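# Shared fixtures (built in code) and independent oracles.

# the goal-24 games of the worked comparison: A(6, 1/3), B(6, 0.3), C(4, 0.5)
g24_AC <- function(...) {
  decision_game(
    data.frame(label = c("A", "C"), u = c(6, 4), p = c(1 / 3, 0.5)),
    goal = 24, ...
  )
}
g24_BC <- function(...) {
  decision_game(
    data.frame(label = c("B", "C"), u = c(6, 4), p = c(0.3, 0.5)),
    goal = 24, ...
  )
}

# the classic paired lottery problems: A over B, D over C
kt_problems <- function() {
  data.frame(
    chosen_u = c(4000, 3000), chosen_p = c(0.2, 1),
    rejected_u = c(3000, 4000), rejected_p = c(0.25, 0.8)
  )
}

# fix-strategy CDF oracle: the goal is reached within t periods iff at
# least n = g/m of the t independent trials succeed (negative-binomial /
# binomial duality)
fix_cdf_binomial <- function(t, p, n_needed) {
  pbinom(n_needed - 1, t, p, lower.tail = FALSE)
}

# brute-force version of the same quantity: enumerate all 2^t win/lose
# sequences and add up the probability of those with >= n_needed wins
fix_cdf_enumerate <- function(t, p, n_needed) {
  if (t == 0) return(as.numeric(n_needed <= 0))
  grid <- expand.grid(rep(list(c(0, 1)), t))
  wins <- rowSums(grid)
  probs <- apply(grid, 1, function(x) prod(ifelse(x == 1, p, 1 - p)))
  sum(probs[wins >= n_needed])
}

# a random valid strategy on any game (seeded by the caller)
random_strategy <- function(game) {
  k_at <- vapply(game$options_at, nrow, 1L)
  rows <- purrr::imap_dfr(game$options_at, function(at, idx) {
    if (nrow(at) == 0) return(NULL)
    w <- stats::rgamma(nrow(at), 1)
    data.frame(stage = idx - 1L, u = at$u, weight = w / sum(w))
  })
  custom_strategy(game, rows)
}
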