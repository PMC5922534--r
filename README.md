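# goalreach

Goal- and time-based analysis of repeated choice under risk.

## The problem

Expected-utility theory cannot separate options with the same expected
value — a prospect $A(6, 1/3)$ (win 6 with probability 1/3, else nothing)
and $C(4, 0.5)$ both average 2 — and it labels people "inconsistent" when
they prefer $(4000, 0.2)$ over $(3000, 0.25)$ yet $(3000, 1)$ over
$(4000, 0.8)$. `goalreach` implements a decision-network model that
resolves both puzzles by adding two ingredients every planner actually
has: a **goal** $G$ and a **deadline** $t$.

Repeated choice becomes a walk on a stage lattice toward the goal. A
payoff table $(u_j, p_j)$ and $G$ define a game matrix $Q$ of per-link
success probabilities; a strategy matrix $W$ (row-stochastic weights over
the options available at each stage) encodes the decision maker's policy;
their composition

$$A = Q \circ W + D$$

($\circ$ the Hadamard product, $D$ the diagonal of staying probabilities)
is a lower-triangular, row-stochastic transition matrix with an absorbing
goal. Iterating $R(t+1) = R(t)A$ yields the decision criterion

$$P_{com}(t) = r_0(t),$$

the probability of having reached the goal within $t$ decision periods.
Curves of options with equal expected utility *interlace*: the riskier
option leads before the crossing, the safer one after — so urgency
rationally favors risk, patience rationally favors safety, and the
"inconsistent" lottery pattern is what a $P_{com}$-maximizer with a goal
in mind would do.

The package is written for quantitative behavioral/decision scientists:
tibble-in/tibble-out functions, `tidy()`/`glance()` summaries,
`autoplot()` figures, plus a small CLI (`exec/goalreach`) for scripted
runs.

## Worked example

The goal-24 game with options $A(6, 1/3)$ and $C(4, 0.5)$, each played as
a *fix* strategy (always the same option), reduces to band-matrix chains
whose curves answer "which option, for which deadline?":

```r
library(goalreach)

gAC <- decision_game(
  data.frame(label = c("A", "C"), u = c(6, 4), p = c(1 / 3, 0.5)),
  goal = 24
)
curve_A <- curve_from_matrix(reduce_fix_chain(gAC, 6))
curve_C <- curve_from_matrix(reduce_fix_chain(gAC, 4))

interlace_time(curve_A, curve_C)
#> [1] 12

glance(curve_A)
#> # A tibble: 1 × 6
#>   strategy horizon cdf_final mean_hitting_time   tau mean_real_time
#>   <chr>      <dbl>     <dbl>             <dbl> <dbl>          <dbl>
#> 1 fix(3)        74     1.000                12     1             12
```

Both options need 12 periods on average, and their CDFs cross exactly
there: before $t = 12$ the riskier A gives the higher probability of
having arrived, after it the safer C does. On the **standard game**
(options $(i, 1/i)$ at $S_i$, all with expected utility 1) the five named
strategies order the same way:

```r
compare_strategies(
  standard_game(10),
  c("max_k", "risky", "random", "safe", "min_k")
)
#> <strategy_comparison>
#> early ranking (t in [1, 9]): max_k > risky > random > safe > min_k
#> late ranking  (t in [13, 197]): min_k > safe > random > risky > max_k
#> # A tibble: 10 × 6
#>    x      y      interlace leader_before leader_after indistinguishable
#>    <chr>  <chr>      <int> <chr>         <chr>        <lgl>
#>  1 max_k  risky         12 max_k         risky        FALSE
#>  2 max_k  random        12 max_k         random       FALSE
#>  3 max_k  safe          12 max_k         safe         FALSE
#>  4 max_k  min_k         10 max_k         min_k        FALSE
#> # … six further pairs
```

Every one of those strategies has mean hitting time exactly 10 (Wald's
identity: unit expected progress per period); they differ only in *when*
the arrival probability accumulates. Other entry points:

* `goal_curve(game, strategy)` — CDF/PMF tibble with auto-horizon;
* `mean_hitting_time()` — exact fundamental-matrix solve;
* `dominance()` — uniform-ordering verdict for option pairs;
* `search_strategy()` — grid or seeded-Dirichlet search for a deadline;
* `estimate_goal_window()` — deadlines consistent with observed choices;
* `simulate_walks()` + `agreement_test()` — seeded Monte-Carlo
  cross-check against the iteration (DKW bound);
* `make_fixtures()` — the worked games as JSON files.

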