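test_that("zero random-effect variance reduces to a plain Poisson fit", {
  cfg <- experiment_config(n_participants = 150, sigma_u = 0)
  ed <- generate_experiment_dataset(cfg, seed = 3)
  m <- fit_poisson_glmm(ed$rounds, ed$participants, "covert",
                        arm = "cross_partisan", re = "participant",
                        nAGQ = 1)
  g <- stats::glm(y ~ outgroup_f + cost_f + age + gender + race +
                    education + political_group,
                  family = stats::poisson(), data = m$data)
  expect_equal(unname(lme4::fixef(m$fit)), unname(stats::coef(g)),
               tolerance = 1e-6)
})

test_that("intercept-only model on constant counts recovers log k", {
  rounds <- data.frame(participant_id = rep(sprintf("p%02d", 1:20), each = 4),
                       outgroup_size = rep(c(1, 4, 6, 9), 20),
                       cost_condition = 1,
                       n_covert_shared = 3L, n_overt_shared = 0L,
                       n_total = 3L)
  participants <- data.frame(participant_id = sprintf("p%02d", 1:20),
                             audience_arm = "cross_partisan")
  expect_message(
    m <- fit_poisson_glmm(rounds, participants, "covert",
                          conditions = character(0),
                          covariates = character(0),
                          re = "participant", nAGQ = 1),
    "constant response")
  expect_equal(unname(covertsig:::model_fixef(m)[["(Intercept)"]]), log(3),
               tolerance = 1e-8)
})

test_that("BIC bookkeeping and Bayes-factor identities hold", {
  ed <- generate_experiment_dataset(experiment_config(n_participants = 80),
                                    seed = 6)
  m <- fit_poisson_glmm(ed$rounds, ed$participants, "covert",
                        arm = "copartisan", re = "participant", nAGQ = 1)
  expect_equal(m$BIC, -2 * m$loglik + m$k * log(m$N))
  expect_equal(m$N, sum(ed$participants$audience_arm == "copartisan") * 8)

  # self-comparison is exactly 1; equal BICs give 1
  expect_identical(bic_bayes_factor(m, m), 1)

  m0 <- fit_poisson_glmm(ed$rounds, ed$participants, "covert",
                         arm = "copartisan", conditions = "cost",
                         re = "participant", nAGQ = 1)
  bf <- bic_bayes_factor(m0, m)
  expect_equal(bf, exp((m$BIC - m0$BIC) / 2))

  # mismatched data is an error
  ed2 <- generate_experiment_dataset(experiment_config(n_participants = 40),
                                     seed = 6)
  m_other <- fit_poisson_glmm(ed2$rounds, ed2$participants, "covert",
                              arm = "copartisan", re = "participant",
                              nAGQ = 1)
  expect_error(bic_bayes_factor(m0, m_other), "different numbers")
})

test_that("null-model margins are flat and match the mean count", {
  ed <- generate_experiment_dataset(experiment_config(n_participants = 80),
                                    seed = 7)
  m0 <- fit_poisson_glmm(ed$rounds, ed$participants, "covert",
                         arm = "copartisan", conditions = character(0),
                         covariates = character(0), re = "participant",
                         nAGQ = 5)
  mg <- average_predictive_margins(m0,
                                   grid = data.frame(outgroup_size =
                                                       c(1, 4, 6, 9)))
  expect_equal(mg$margin, rep(mg$margin[1], 4))
  expect_equal(mg$margin[1], mean(m0$data$y), tolerance = 0.01)
  expect_true(all(mg$lower <= mg$margin & mg$margin <= mg$upper))
})

test_that("margins are invariant to duplicating the sample", {
  ed <- generate_experiment_dataset(experiment_config(n_participants = 60),
                                    seed = 8)
  m <- fit_poisson_glmm(ed$rounds, ed$participants, "covert",
                        arm = "cross_partisan", re = "participant",
                        nAGQ = 1)
  grid <- data.frame(outgroup_size = c(1, 9))
  m1 <- average_predictive_margins(m, grid)
  doubled <- m
  doubled$data <- rbind(m$data, m$data)
  m2 <- average_predictive_margins(doubled, grid)
  expect_equal(m1$margin, m2$margin, tolerance = 1e-12)
})

test_that("AMEs are antisymmetric, zero on equal cells, and warn off-grid", {
  ed <- generate_experiment_dataset(experiment_config(n_participants = 60),
                                    seed = 10)
  m <- fit_poisson_glmm(ed$rounds, ed$participants, "covert",
                        arm = "cross_partisan", re = "participant",
                        nAGQ = 1)
  ab <- average_marginal_effect(m, list(outgroup_size = 1),
                                list(outgroup_size = 9))
  ba <- average_marginal_effect(m, list(outgroup_size = 9),
                                list(outgroup_size = 1))
  expect_equal(ab$ame, -ba$ame)
  expect_equal(ab$se, ba$se)

  same <- average_marginal_effect(m, list(outgroup_size = 4),
                                  list(outgroup_size = 4))
  expect_equal(same$ame, 0)
  expect_equal(same$se, 0)

  expect_warning(
    average_predictive_margins(m, grid = data.frame(outgroup_size = 5)),
    "not observed")
})

test_that("planted condition effects are recovered within 3 SE", {
  cfg <- experiment_config(n_participants = 240)
  ed <- generate_experiment_dataset(cfg, seed = 12)
  m <- fit_poisson_glmm(ed$rounds, ed$participants, "covert",
                        arm = "cross_partisan", re = "participant",
                        nAGQ = 1)
  beta <- lme4::fixef(m$fit)
  se <- sqrt(diag(as.matrix(stats::vcov(m$fit))))
  for (s in c("4", "6", "9")) {
    planted <- log(cfg$covert_out_mult[[s]])
    term <- paste0("outgroup_f", s)
    expect_lt(abs(beta[[term]] - planted), 3 * se[[term]])
  }
  ame <- average_marginal_effect(m, list(outgroup_size = 1),
                                 list(outgroup_size = 9))
  expect_lt(abs(ame$ame - 0.73), 3 * ame$se)
})
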