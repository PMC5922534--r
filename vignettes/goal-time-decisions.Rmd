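---
title: "Goal- and time-based analysis of decisions under risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Goal- and time-based analysis of decisions under risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(goalreach)
```

## The model

Expected utility is silent between options with the same expected value:
a prospect paying 6 with probability 1/3 and one paying 4 with probability
1/2 both "average" 2, yet people reliably prefer one or the other depending
on circumstances. `goalreach` implements a resolution: treat repeated risky
choice as a walk toward a **goal** and score options by the probability of
having *arrived* within a deadline, not by per-step averages.

A payoff table of options $(u_j, p_j)$ — win $u_j$ with probability $p_j$,
else nothing — and a goal $G$ define a stage lattice. In *Approaching*
mode the state $S_k$ means $k$ stages remain; taking option $j$ at $S_k$
moves to $S_{k-j}$ with probability $p_j$ and stays at $S_k$ otherwise.
The *Growing* mode counts upward from $S_0$ instead; the two are the same
chain under the relabelling $S_k \leftrightarrow S_{g-k}$, which the test
suite verifies by direct matrix comparison.

Three matrices carry the whole computation:

* the **game matrix** $Q$, with $q_{ij} = p_{i-j}$ the per-link success
  probability implied by the payoff table;
* the **strategy matrix** $W$, with $b_{ij} = {}^i w_{i-j}$ the weight the
  decision maker puts at $S_i$ on the option of utility $i - j$; each row
  sums to 1;
* their composition $A = Q \circ W + D$ ("$\circ$" the Hadamard product),
  with the diagonal $D$ holding the staying mass
  $\sum_m {}^i w_m (1 - p_m)$. $A$ is lower-triangular and row-stochastic,
  and the goal row is absorbing.

Iterating the occupancy vector $R(t+1) = R(t) A$ from point mass at the
start stage and reading the goal entry gives the decision criterion
$P_{com}(t) = r_0(t)$: the probability of having reached the goal within
$t$ decision periods. Its increments are the first-passage distribution
$P(t)$. Real time is $t \tau$, with $\tau$ the (metadata-only) seconds per
decision.

## Strategies

Six policies have closed-form weights on the **standard game**, where
$S_k$ offers $(i, 1/i)$ for $i = 1..k$ so that every option has expected
utility exactly 1:

| strategy | weight on $(k, 1/k)$ at $S_i$ | character |
|----------|-------------------------------|-----------|
| `fix` | all on one option $(m, p_m)$ | reduced $g/m + 1$-node band chain |
| `min_k` | all on $(1, 1)$ | sure arrival at exactly $t = g$ |
| `max_k` | all on $(i, 1/i)$ | $P_{com}(t) = 1 - (1 - 1/g)^t$ |
| `risky` | $2k / (i(i+1))$ | proportional to utility |
| `random` | $1/i$ | uniform |
| `safe` | $(1/k) / H_i$ | proportional to probability |

Because every standard-game option advances one stage per period in
expectation, **every** strategy's mean hitting time is exactly the goal
$g$ (Wald's identity); the curves differ only in spread. What separates
strategies is *when* the probability mass arrives: riskier weightings
front-load $P_{com}$, safer ones back-load it, and all CDF pairs interlace
once. On `standard_game(10)`:

```{r}
cmp <- compare_strategies(
  standard_game(10),
  c("max_k", "risky", "random", "safe", "min_k")
)
cmp$early_ranking
cmp$late_ranking
```

This is the model's reading of risk attitude: urgency (a deadline before
the interlace) makes the risky choice the rational one, patience makes the
safe choice rational, with no inconsistency involved.

## Worked comparison: equal expected utilities

For the goal-24 game with $A(6, 1/3)$ and $C(4, 0.5)$ — both expected
utility 2 — the fix-strategy chains give:

```{r}
gAC <- decision_game(
  data.frame(label = c("A", "C"), u = c(6, 4), p = c(1 / 3, 0.5)),
  goal = 24
)
curve_A <- curve_from_matrix(reduce_fix_chain(gAC, 6))
curve_C <- curve_from_matrix(reduce_fix_chain(gAC, 4))
interlace_time(curve_A, curve_C)
mean_hitting_time(reduce_fix_chain(gAC, 6))
```

Both options average 12 periods, and the curves cross exactly there: A is
preferable to a decision maker in a hurry, C to a patient one. Against
$B(6, 0.3)$, option C crosses at $t = 10$ and thereafter leads — a
preference for B before that point means accepting a *lower* expected
utility to raise the chance of early arrival, which is the behavioral
pattern the model sets out to rationalize.

## Parameters and defaults

* **Stage unit.** Utilities and the goal are converted to integer stages
  by their greatest common divisor; incommensurable inputs are rejected
  rather than rounded, because the lattice model is defined on integers.
  An explicit `stage_unit` (any exact common divisor) selects a finer
  lattice; every curve, crossing and hitting time is invariant to that
  choice, which the tests confirm by comparing the unit-1 and gcd
  lattices.
* **Overshoot.** An option whose utility exceeds the stages remaining is,
  by default, aimed at the goal (`"clamp"`): winning more than needed is
  still arrival. `"strict"` removes such options instead, reproducing the
  textbook picture in which $S_k$ offers exactly $k$ options. The named
  strategies and every worked example are unaffected (their routes never
  overshoot); the choice matters only for broad weightings near the goal.
* **Fix divisibility.** `named_strategy(..., "fix", m)` requires $m$ to
  divide the goal — the route is otherwise undefined on the strict
  lattice. Goal-window estimation builds its per-option curves with
  clamping, so it remains defined for any commensurable option.
* **Tie tolerance (1e-12).** Two CDF values closer than this are treated
  as tied: ties neither establish a leader nor count as a crossing, which
  prevents floating-point ordering artifacts near saturation. The row-sum
  stochasticity check uses 1e-10 per row.
* **Auto-horizon (tail 1e-9, cap 1e6).** Curves extend until the
  unabsorbed mass falls below `epsilon`; absorption tails are geometric,
  so this terminates quickly for every strategy with positive progress.
  A chain that cannot absorb raises an error rather than iterating
  forever.
* **Mean hitting times** come from the fundamental-matrix solve
  $(I - T)\,n = \mathbf{1}$ on the transient block (restricted to stages
  reachable from the start, so strict-mode dead stages are harmless); the
  truncated-sum estimate is kept as a `method = "truncated"` cross-check.

## Strategy search

With $g(g+1)/2$ free weights and $g + 1$ constraints, the best stationary
$W$ for a deadline is analytically available only for tiny games, so
`search_strategy()` evaluates trial weightings: an exhaustive simplex grid
per stage for $g \le 4$ (resolution chosen to fit the candidate budget),
or seeded Dirichlet(1) draws for anything larger. Scoring is
$P_{com}(\text{objective}_t)$; ties break to the first candidate, and the
random family is reproducible given its seed. On `standard_game(2)` with a
one-period deadline the search recovers the analytic optimum (all weight
on $(2, 1/2)$, $P_{com}(1) = 0.5$); with a long deadline it switches to
sure stepping, which reaches certainty at $t = 2$.

## Reading goals off observed choices

`estimate_goal_window()` inverts the model: given choices (one option
preferred over another) and a candidate goal, it reports the deadlines $t$
at which every chosen option's $P_{com}$ strictly exceeds its rejected
alternative's. For the classic paired lotteries — $(4000, 0.2)$ preferred
to $(3000, 0.25)$, and $(3000, 1)$ preferred to $(4000, 0.8)$ — a goal of
12000 yields a non-empty window opening at $t = 4$, the first period at
which the sure option has arrived while the risky one still may not have:

```{r}
kt <- data.frame(
  chosen_u = c(4000, 3000), chosen_p = c(0.2, 1),
  rejected_u = c(3000, 4000), rejected_p = c(0.25, 0.8)
)
estimate_goal_window(kt, 12000)
```

Windows are reported only while the curves are numerically
distinguishable: once a difference falls below the tie tolerance the
window closes, so an interval that is mathematically half-infinite (a sure
option against a merely-almost-sure one) is truncated where both CDFs
agree to twelve decimals. Published illustrations of this construction
quote somewhat different endpoints for these problems under an indexing
convention we could not reconstruct; the package reports the windows its
own stated conventions produce, and the tests pin the derived properties
(the window opens at $t = 4$; a single pair's window closes one period
before its curves interlace).

## Dominance

Between fix strategies, option X dominates Y — $P_{comX} \ge P_{comY}$ at
every $t$ — exactly when X is no worse on both coordinates and strictly
better in expected utility: reaching the goal then needs no more
successes at a no-worse per-trial rate. When $(u_X - u_Y)(p_X - p_Y) < 0$
the curves interlace and the preference is genuinely time-dependent.
A disjunctive reading of the criterion ("no worse on *either*
coordinate") would misclassify interlacing pairs such as $B(6, 0.3)$ vs
$C(4, 0.5)$, so the conjunction is used and is property-tested against
full iteration on random option pairs.

## The Monte-Carlo cross-check

`simulate_walks()` replays the same process stochastically: walkers draw
an option by the strategy weights and advance or stay. The ensemble is
simulated synchronously — all walkers advance one period per sweep,
sampled stage-by-stage from the composed transition row — from a single
seeded stream. This choice is vectorised (one `sample()` call per occupied
stage per period) and exactly reproducible given the seed; what it gives
up is only per-walker stream independence, which nothing in the package
depends on. Agreement with the matrix iteration is judged by the
Dvoretzky–Kiefer–Wolfowitz bound $\sqrt{\ln(2/\alpha) / (2n)}$ at 99%
confidence; censored walkers stay in the empirical CDF's denominator but
are excluded from mean hitting times.

The simulator doubles as the package's synthetic-data generator, and its
defaults mirror the worked study conditions: standard games with goals 10,
50 and 100, the goal-24 fix comparison, and the paired-lottery problems
(regenerable via `make_fixtures()`). What these conditions do *not*
emulate is anything behavioral: there is no choice noise, no learning of
$(u, p)$, no time-varying strategy, and utilities equal monetary values
(no curvature). Passing tests therefore certify the mathematics of the
chain and its comparisons, not a fit to human data.

## Problem sizes

The test suite and the acceptance script run dense matrices up to
101 × 101 and horizons up to a few thousand periods, with Monte-Carlo
ensembles of $10^4$–$10^5$ walkers — the scales at which the model's
published comparisons live, and comfortable for a laptop. The iteration
is $O(T g^2)$ and the simulation $O(T \cdot \#\text{stages})$ per sweep,
so far larger games are feasible; only the exhaustive grid search grows
combinatorially, which is why it is restricted to $g \le 4$.

## Known limitations

* Strategies are stationary: $W$ does not depend on $t$.
* Growing mode applies the payoff table at every non-absorbing stage
  (absorbing at any index $\ge g$); the original construction specifies
  options only at the origin, and other extensions are conceivable.
* `game_matrix()` cannot represent two clamped options sharing a
  destination (the per-link probability is then ambiguous); the
  option-level `transition_matrix()` handles such games, and the Hadamard
  route `compose_transition()` agrees with it whenever $Q$ is well
  defined.
* No inference of $(u, p)$ from observed trajectories, and no
  multi-player extension.
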