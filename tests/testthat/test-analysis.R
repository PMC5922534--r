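test_that("fix-strategy CDF curves interlace at the expected times", {
  cvA <- curve_from_matrix(reduce_fix_chain(g24_AC(), 6))
  cvC <- curve_from_matrix(reduce_fix_chain(g24_AC(), 4))
  expect_equal(as.integer(interlace_time(cvA, cvC)), 12L)

  cvB <- curve_from_matrix(reduce_fix_chain(g24_BC(), 6))
  cvC2 <- curve_from_matrix(reduce_fix_chain(g24_BC(), 4))
  expect_equal(as.integer(interlace_time(cvB, cvC2)), 10L)

  # symmetric up to leader labels, invariant under horizon extension
  cmp <- compare_curves(cvA, cvC)
  cmp_rev <- compare_curves(cvC, cvA)
  expect_equal(cmp$interlace, cmp_rev$interlace)
  expect_equal(cmp$leader_before, cmp_rev$leader_before)
  long_A <- curve_from_matrix(reduce_fix_chain(g24_AC(), 6), horizon = 400)
  long_C <- curve_from_matrix(reduce_fix_chain(g24_AC(), 4), horizon = 400)
  expect_equal(as.integer(interlace_time(long_A, long_C)), 12L)

  # identical curves are flagged, not crossed
  self <- interlace_time(cvA, cvA)
  expect_true(is.na(self))
  expect_true(attr(self, "indistinguishable"))
})

test_that("dominance follows the u/p/expected-utility criterion", {
  A <- list(u = 6, p = 1 / 3)
  B <- list(u = 6, p = 0.3)
  C <- list(u = 4, p = 0.5)
  expect_equal(dominance(A, B), "first")
  expect_equal(dominance(B, A), "second")
  expect_equal(dominance(A, C), "none") # equal expected utility
  expect_equal(dominance(B, C), "none") # time-dependent preference
  expect_equal(dominance(A, A), "none") # e_X > e_X is false

  # dominance implies uniform CDF ordering under fix strategies
  withr::local_seed(99)
  for (rep in 1:6) {
    u <- sample(1:6, 2, replace = TRUE)
    p <- round(runif(2, 0.05, 1), 2)
    g <- u[1] * u[2] * sample(1:3, 1)
    verdict <- dominance(list(u = u[1], p = p[1]), list(u = u[2], p = p[2]))
    if (verdict == "none") next
    cdf1 <- fix_cdf_binomial(0:300, p[1], g / u[1])
    cdf2 <- fix_cdf_binomial(0:300, p[2], g / u[2])
    if (verdict == "first") {
      expect_true(all(cdf1 - cdf2 >= -1e-12))
    } else {
      expect_true(all(cdf2 - cdf1 >= -1e-12))
    }
  }
  # and for the printed pair: A's curve never falls below B's
  cvA <- curve_from_matrix(reduce_fix_chain(g24_AC(), 6), horizon = 500)
  cvB <- curve_from_matrix(reduce_fix_chain(g24_BC(), 6), horizon = 500)
  expect_true(all(cvA$cdf - cvB$cdf >= -1e-12))
})

test_that("strategy comparison ranks risky-to-safe early and reverses late", {
  cmp <- compare_strategies(
    standard_game(10),
    c("max_k", "risky", "random", "safe", "min_k")
  )
  expect_equal(cmp$early_ranking, c("max_k", "risky", "random", "safe", "min_k"))
  expect_equal(cmp$late_ranking, rev(c("max_k", "risky", "random", "safe", "min_k")))

  # explicit spot checks inside each window
  cdf_at <- function(nm, tt) {
    with(cmp$curves, cdf[strategy == nm & t == tt])
  }
  for (tt in c(5, 8)) {
    vals <- vapply(c("max_k", "risky", "random", "safe", "min_k"), cdf_at, 1, tt = tt)
    expect_true(all(diff(vals) < 0))
  }
  for (tt in c(15, 25)) {
    vals <- vapply(c("max_k", "risky", "random", "safe", "min_k"), cdf_at, 1, tt = tt)
    expect_true(all(diff(vals) > 0))
  }

  # duplicated strategy is reported indistinguishable
  sg <- standard_game(6)
  dup <- compare_strategies(
    sg,
    list(a = named_strategy(sg, "risky"), b = named_strategy(sg, "risky"))
  )
  expect_true(all(dup$pairwise$indistinguishable))
})

test_that("strategy search finds the deadline-optimal weights", {
  # g = 2, deadline t = 1: everything on (2, 1/2); P_com(1) = 1/2
  res <- search_strategy(standard_game(2), objective_t = 1, family = "grid")
  expect_equal(res$value, 0.5)
  expect_equal(res$strategy$weights[[3]], c(0, 1))

  # long deadline: sure stepping reaches 1 by t = 2, beating max k's 3/4
  res2 <- search_strategy(standard_game(2), objective_t = 2, family = "grid")
  expect_equal(res2$value, 1)
  expect_equal(res2$strategy$weights[[3]], c(1, 0))
  maxk_cdf2 <- goal_curve(standard_game(2), "max_k", horizon = 2)$cdf[3]
  expect_equal(maxk_cdf2, 0.75)

  # degenerate game: only (1, 1)
  res3 <- search_strategy(standard_game(1), objective_t = 1, family = "grid")
  expect_equal(res3$value, 1)

  # seeded random search is deterministic and never beats the grid envelope
  sg3 <- standard_game(3)
  for (obj in c(2, 4)) {
    grid <- search_strategy(sg3, obj, family = "grid", n_trials = 1000)
    rand1 <- search_strategy(sg3, obj, family = "dirichlet_random",
      n_trials = 150, seed = 5
    )
    rand2 <- search_strategy(sg3, obj, family = "dirichlet_random",
      n_trials = 150, seed = 5
    )
    expect_equal(rand1$value, rand2$value)
    expect_identical(rand1$strategy$weights, rand2$strategy$weights)
    expect_lte(rand1$value, grid$value + 5e-3)
  }
  expect_error(search_strategy(sg3, 2, n_trials = 0), "n_trials")
  expect_error(search_strategy(standard_game(5), 2, family = "grid"), "g > 4")
})

test_that("goal-window estimation recovers the urgency range behind choices", {
  win <- estimate_goal_window(kt_problems(), 12000)
  expect_equal(nrow(win), 1L)
  # the sure option D arrives at t = 4 while C is still short of certainty
  expect_equal(win$start, 4)

  # chosen identical to rejected: no window
  same <- data.frame(
    chosen_u = 3000, chosen_p = 1, rejected_u = 3000, rejected_p = 1
  )
  expect_equal(nrow(estimate_goal_window(same, 12000)), 0L)

  # single pair: window closes one period before the curves interlace
  one <- kt_problems()[1, ]
  win1 <- estimate_goal_window(one, 12000)
  cvA <- goalreach:::.single_option_curve(4000, 0.2, 12000)
  cvB <- goalreach:::.single_option_curve(3000, 0.25, 12000)
  t_int <- as.integer(interlace_time(cvA, cvB))
  expect_equal(win1$end[nrow(win1)], t_int - 1)
  # brute-force cross-check of the same endpoint
  d <- fix_cdf_binomial(0:60, 0.2, 3) - fix_cdf_binomial(0:60, 0.25, 4)
  expect_equal(win1$end[nrow(win1)], max(which(d > 1e-12)) - 1)

  expect_error(estimate_goal_window(data.frame(x = 1), 100), "columns")
})

test_that("the overlap bound on inconsistent responders is max(0, p + q - 1)", {
  expect_equal(inconsistency_lower_bound(0.65, 0.80), 0.45)
  expect_equal(inconsistency_lower_bound(0.5, 0.5), 0)
  expect_equal(inconsistency_lower_bound(1, 1), 1)
  expect_equal(inconsistency_lower_bound(0.2, 0.3), 0)
  expect_error(inconsistency_lower_bound(1.2, 0.5), "\\[0, 1\\]")
  expect_error(inconsistency_lower_bound(0.5, -0.1), "\\[0, 1\\]")
})
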