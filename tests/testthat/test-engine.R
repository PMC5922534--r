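test_that("composed transition matrices match their closed forms", {
  # max k: effective two-state system {S_g, S_0}: [[1, 0], [1/g, 1 - 1/g]]
  for (g in c(4, 10, 25)) {
    sg <- standard_game(g)
    A <- transition_matrix(sg, named_strategy(sg, "max_k"))
    eff <- A[c(1, g + 1), c(1, g + 1)]
    expect_equal(unname(eff), rbind(c(1, 0), c(1 / g, 1 - 1 / g)))
    expect_equal(unname(A[g + 1, 2:g]), rep(0, g - 1))
  }

  # fix (m, p): band matrix on the reduced chain, p below the diagonal
  gAC <- g24_AC()
  B <- reduce_fix_chain(gAC, 6)
  expect_equal(dim(B), c(5, 5)) # S_24 -> S_18 -> S_12 -> S_6 -> S_0
  expect_equal(unname(B[cbind(2:5, 1:4)]), rep(1 / 3, 4))
  expect_equal(unname(diag(B)), c(1, rep(2 / 3, 4)))
  expect_equal(dim(reduce_fix_chain(gAC, 4)), c(7, 7)) # six-stage route
  expect_error(reduce_fix_chain(standard_game(10), 3), "Route undefined")
  # g = m: exactly the max k two-state matrix
  g1 <- decision_game(data.frame(u = 8, p = 1 / 8), 8)
  expect_equal(
    unname(unclass(reduce_fix_chain(g1, 8))),
    rbind(c(1, 0), c(1 / 8, 7 / 8)),
    ignore_attr = TRUE
  )

  # min k: sure advance, no staying mass off the goal
  sg <- standard_game(5)
  A <- transition_matrix(sg, named_strategy(sg, "min_k"))
  expect_equal(unname(A[cbind(2:6, 1:5)]), rep(1, 5))
  expect_equal(unname(diag(A)), c(1, rep(0, 5)))
})

test_that("row-stochasticity survives composition for random strategies", {
  withr::local_seed(42)
  for (rep in 1:5) {
    g <- sample(3:30, 1)
    sg <- standard_game(g)
    A <- transition_matrix(sg, random_strategy(sg))
    expect_equal(unname(rowSums(A)), rep(1, g + 1), tolerance = 1e-10)
    expect_true(all(A >= 0))
    expect_true(all(A[upper.tri(A)] == 0))
  }
  # and on a non-standard clamped game
  withr::local_seed(7)
  A <- transition_matrix(g24_AC(stage_unit = 1), random_strategy(g24_AC(stage_unit = 1)))
  expect_equal(unname(rowSums(A)), rep(1, 25), tolerance = 1e-10)
})

test_that("iteration conserves probability and reproduces single steps", {
  sg <- standard_game(10)
  A <- transition_matrix(sg, named_strategy(sg, "max_k"))
  R <- iterate_states(A, 1)
  expect_equal(R[2, 1], 0.1) # r_0(1)
  expect_equal(R[2, 11], 0.9) # r_g(1)

  sg3 <- standard_game(3)
  R3 <- iterate_states(transition_matrix(sg3, named_strategy(sg3, "min_k")), 3)
  expect_equal(unname(R3[4, ]), c(1, 0, 0, 0))

  withr::local_seed(1)
  Ar <- transition_matrix(sg, random_strategy(sg))
  Rr <- iterate_states(Ar, 50)
  expect_equal(unname(rowSums(Rr)), rep(1, 51), tolerance = 1e-10)
  expect_error(iterate_states(Ar, 0), "positive integer")
})

test_that("max k CDF equals the geometric closed form", {
  for (g in c(3, 10, 100)) {
    sg <- standard_game(g)
    cv <- goal_curve(sg, "max_k", horizon = 1000)
    expect_equal(cv$cdf, 1 - (1 - 1 / g)^(0:1000), tolerance = 1e-12)
  }
})

test_that("min k first-passage mass is a delta at t = g", {
  sg <- standard_game(7)
  cv <- goal_curve(sg, "min_k", horizon = 15)
  expect_equal(cv$pmf, as.numeric(0:15 == 7))
  expect_equal(cv$cdf, as.numeric(0:15 >= 7))
})

test_that("fix CDF equals the binomial-tail oracle", {
  # brute-force enumeration and pbinom agree with each other and with the
  # band-matrix iteration
  gAC <- g24_AC()
  cvA <- curve_from_matrix(reduce_fix_chain(gAC, 6), horizon = 12)
  for (t in c(0, 3, 7, 12)) {
    expect_equal(cvA$cdf[t + 1], fix_cdf_enumerate(t, 1 / 3, 4), tolerance = 1e-12)
  }
  long <- curve_from_matrix(reduce_fix_chain(gAC, 6), horizon = 200)
  expect_equal(long$cdf, fix_cdf_binomial(0:200, 1 / 3, 4), tolerance = 1e-12)
  cvC <- curve_from_matrix(reduce_fix_chain(gAC, 4), horizon = 200)
  expect_equal(cvC$cdf, fix_cdf_binomial(0:200, 0.5, 6), tolerance = 1e-12)
})

test_that("reduced fix chain and full-lattice composition give identical curves", {
  fine <- g24_AC(stage_unit = 1)
  for (m in c(6, 4)) {
    full <- goal_curve(fine, "fix", fix_utility = m, horizon = 100)
    red <- curve_from_matrix(reduce_fix_chain(fine, m), horizon = 100)
    expect_equal(full$cdf, red$cdf, tolerance = 1e-12)
  }
})

test_that("auto-horizon stops once the unreached tail is below epsilon", {
  sg <- standard_game(30)
  cv <- goal_curve(sg, "risky")
  expect_lt(1 - cv$cdf[nrow(cv)], 1e-9)
  expect_true(all(diff(cv$cdf) >= 0))
  expect_true(all(cv$pmf >= 0))
  expect_equal(cv$pmf, c(cv$cdf[1], diff(cv$cdf)))
})

test_that("mean hitting time: fundamental matrix, closed forms, Wald identity", {
  # fix (m, p): g/m geometric(p) waits
  gAC <- g24_AC()
  expect_equal(mean_hitting_time(reduce_fix_chain(gAC, 6)), 12)
  expect_equal(mean_hitting_time(reduce_fix_chain(gAC, 4)), 12)
  # truncated-sum cross-check agrees with the exact solve
  expect_equal(
    mean_hitting_time(reduce_fix_chain(gAC, 6), method = "truncated"),
    12,
    tolerance = 1e-6
  )
  # brute-force truncated expectation of a sum of geometric waits
  p <- 1 / 3
  tt <- 4:600 # 4th success at period t
  pmf_t <- dbinom(3, tt - 1, p) * p
  expect_equal(sum(tt * pmf_t), 12, tolerance = 1e-6)

  # min k on goal g: exactly g
  sg <- standard_game(9)
  expect_equal(mean_hitting_time(sg, "min_k"), 9)

  # Wald identity: every strategy on a standard game has mean exactly g
  withr::local_seed(11)
  for (g in c(5, 17, 60)) {
    sgg <- standard_game(g)
    for (nm in c("min_k", "max_k", "risky", "random", "safe")) {
      expect_equal(mean_hitting_time(sgg, nm), g, tolerance = 1e-8)
    }
    expect_equal(mean_hitting_time(sgg, random_strategy(sgg)), g,
      tolerance = 1e-8
    )
  }

  # a chain that cannot absorb is reported, not silently solved
  dead <- matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE)
  expect_error(
    mean_hitting_time(structure(dead, start = 1L, absorb = 0L)),
    "Non-absorbing"
  )
})

test_that("curve CSV output carries metadata and round-trips numerically", {
  f <- withr::local_tempfile(fileext = ".csv")
  sg <- standard_game(6)
  cv <- goal_curve(sg, "random", horizon = 40)
  write_curves_csv(cv, f)
  header <- readLines(f, n = 3)
  expect_match(header[2], "strategy: random")
  back <- utils::read.csv(f, comment.char = "#")
  expect_equal(back$cdf, cv$cdf)
  expect_equal(back$t, cv$t)
})

test_that("glance reports horizon, tail and mean hitting time", {
  sg <- standard_game(8)
  gl <- glance(goal_curve(sg, "safe"))
  expect_equal(gl$mean_hitting_time, 8, tolerance = 1e-8)
  expect_gt(gl$cdf_final, 1 - 1e-9)
  expect_equal(gl$strategy, "safe")
})
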