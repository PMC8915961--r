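test_that("expected payoffs match hand arithmetic and the member-sum oracle", {
  env <- fig4_env(d = 0.9, c = 1)
  expect_equal(expected_payoff_overt(env), -6.4)
  expect_equal(expected_payoff_covert(env), -3.9)
  expect_equal(payoff_advantage(env)$advantage, 2.5)

  # oracle agreement over a parameter grid
  grid <- expand.grid(d = c(0, 0.3, 0.6, 1), c = c(0.5, 1, 2),
                      w0 = c(0, 340))
  for (i in seq_len(nrow(grid))) {
    env <- fig4_env(d = grid$d[i], c = grid$c[i], w0 = grid$w0[i])
    expect_equal(expected_payoff_overt(env),
                 payoff_by_member_sum(env, "overt"))
    expect_equal(expected_payoff_covert(env),
                 payoff_by_member_sum(env, "covert"))
  }
})

test_that("payoff edge cases behave per the model", {
  all_in <- suppressWarnings(
    signaling_env(n = 10, d = 0, R = 1, r_I = 1, r_O = 0.2, b = 1))
  expect_equal(expected_payoff_overt(all_in), 10)
  expect_equal(expected_payoff_covert(all_in), 10)

  deaf <- suppressWarnings(
    signaling_env(n = 10, d = 0.7, R = 0, r_I = 0, r_O = 0, w0 = 5))
  expect_equal(expected_payoff_overt(deaf), 5)
  expect_equal(expected_payoff_covert(deaf), 5)

  # covert never received -> baseline for any d
  mute_covert <- suppressWarnings(
    signaling_env(n = 10, d = 0.4, R = 0.8, r_I = 0, r_O = 0, w0 = 2))
  expect_equal(expected_payoff_covert(mute_covert), 2)

  # identical reception -> zero advantage everywhere
  same <- suppressWarnings(
    signaling_env(n = 10, d = 0.3, R = 0.8, r_I = 0.8, r_O = 0.8))
  expect_equal(payoff_advantage(same)$advantage, 0)
})

test_that("environment validation rejects malformed parameters", {
  expect_error(signaling_env(n = 0), "positive integer")
  expect_error(signaling_env(n = 2.5), "positive integer")
  expect_error(signaling_env(d = 1.2), "\\[0, 1\\]")
  expect_error(signaling_env(R = 0.5, r_I = 0.6, r_O = 0.2), "r_O <= r_I <= R")
  expect_error(signaling_env(b = -1), "non-negative")
  expect_error(signaling_env(R = 0.8, r_I = 0.8, r_O = 0.5, strict = TRUE),
               "strict")
  expect_warning(signaling_env(R = 0.8, r_I = 0.8, r_O = 0.5), "tied")
})

test_that("covert threshold equals the grid-search root of the advantage", {
  grid_root <- function(env) {
    d <- seq(0, 1, by = 1e-6)
    adv <- payoff_curve(env, c(0, 1))$advantage
    # advantage is affine in d: interpolate the sign change on the fine grid
    a <- adv[1] + (adv[2] - adv[1]) * d
    d[which.min(abs(a))]
  }
  env1 <- fig4_env(c = 1)
  expect_equal(covert_threshold(env1), 0.4)
  expect_equal(covert_threshold(env1), grid_root(env1), tolerance = 1e-6)

  env2 <- fig4_env(c = 0.5)
  expect_equal(covert_threshold(env2), 4 / 7)
  expect_equal(covert_threshold(env2), grid_root(env2), tolerance = 1e-6)

  # covert as good as overt for the ingroup -> threshold at zero
  env3 <- suppressWarnings(
    signaling_env(n = 10, R = 0.8, r_I = 0.8, r_O = 0.5))
  expect_equal(covert_threshold(env3), 0)

  # degenerate: advantage constant in d -> flagged NA, not a number
  env4 <- suppressWarnings(
    signaling_env(n = 10, R = 0.8, r_I = 0.8, r_O = 0.8))
  expect_warning(thr <- covert_threshold(env4), "constant")
  expect_true(is.na(thr))
  expect_true(attr(thr, "all_equal"))
})

test_that("advantage sign agrees with the threshold on both sides", {
  for (c in c(0.5, 1, 2)) {
    env <- fig4_env(c = c)
    dstar <- covert_threshold(env)
    for (d in c(0.05, 0.3, 0.65, 0.99)) {
      if (abs(d - dstar) < 1e-9) next  # exactly at the crossing
      env$d <- d
      expect_equal(sign(payoff_advantage(env)$advantage),
                   sign(d - dstar))
    }
  }
})

test_that("payoff curve is affine, ordered, and validated", {
  env <- fig4_env(c = 1)
  curve <- payoff_curve(env, c(0, 0.9))
  expect_equal(curve$advantage, c(-2.0, 2.5))

  # affine in d: three collinear points
  tri <- payoff_curve(env, c(0.1, 0.45, 0.8))
  expect_equal(tri$advantage[2],
               mean(c(tri$advantage[1], tri$advantage[3])),
               tolerance = 1e-12)

  # strictly increasing when b, c > 0 and R > r_O
  dense <- payoff_curve(env, seq(0, 1, 0.05))
  expect_true(all(diff(dense$advantage) > 0))

  expect_equal(nrow(payoff_curve(env, numeric(0))), 0)
  expect_error(payoff_curve(env, c(0.2, 1.4)), "\\[0, 1\\]")

  # advantage non-decreasing in c for fixed d > 0
  adv_c <- vapply(c(0.25, 0.5, 1, 2), function(c)
    payoff_advantage(fig4_env(d = 0.7, c = c))$advantage, numeric(1))
  expect_true(all(diff(adv_c) >= 0))
})

test_that("mixed strategies interpolate the pure payoffs", {
  env <- fig4_env(d = 0.9, c = 1)
  expect_equal(mixed_strategy_payoff(env, 0), expected_payoff_overt(env))
  expect_equal(mixed_strategy_payoff(env, 1), expected_payoff_covert(env))
  expect_equal(mixed_strategy_payoff(env, 0.4),
               0.4 * -3.9 + 0.6 * -6.4)
  expect_error(mixed_strategy_payoff(env, 1.5), "\\[0, 1\\]")
})

test_that("simulation matches degenerate closed forms and is reproducible", {
  sure <- signaling_env(n = 10, d = 0, R = 1, r_I = 0.9, r_O = 0.5,
                        b = 1, w0 = 3)
  reps <- simulate_signaling_round(sure, "overt", 200, seed = 1)
  expect_true(all(reps == 13))

  silent <- suppressWarnings(
    signaling_env(n = 10, d = 0.5, R = 0.8, r_I = 0, r_O = 0, w0 = 7))
  reps <- simulate_signaling_round(silent, "covert", 200, seed = 1)
  expect_true(all(reps == 7))

  env <- fig4_env(d = 0.9, c = 1)
  a <- simulate_signaling_round(env, "covert", 1000, seed = 42)
  b <- simulate_signaling_round(env, "covert", 1000, seed = 42)
  expect_identical(a, b)

  odd <- fig4_env(d = 0.55, c = 1)
  expect_error(simulate_signaling_round(odd, "overt", 10, seed = 1,
                                        rounding = "error"),
               "not an integer")
  r <- simulate_signaling_round(odd, "overt", 10, seed = 1)
  expect_equal(attr(r, "n_outgroup"), 6L)
  expect_equal(attr(r, "realized_d"), 0.6)
})

test_that("simulation mean converges to the analytic payoff", {
  env <- fig4_env(d = 0.9, c = 1)
  reps <- simulate_signaling_round(env, "covert", 1e5, seed = 7)
  se <- stats::sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - (-3.9)), 3 * se)
})
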