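ties_context <- function() {
  iafit:::new_context("DG", 999, c("a", "b", "c"),
                      x = c(500, 500, 500), y = c(500, 500, 500))
}

test_that("identical seed and config give bit-identical fits", {
  sched <- game_schedule()
  truth <- data.frame(participant_id = "P1", true_alpha = 0.6,
                      true_beta = 0.4, true_lambda = 6)
  ch <- simulate_choices(truth, sched, seed = 21)[, -1]
  f1 <- fit_participant(ch, sched, config = light_mcmc(seed = 5))
  f2 <- fit_participant(ch, sched, config = light_mcmc(seed = 5))
  expect_identical(f1$draws, f2$draws)
  f3 <- fit_participant(ch, sched, config = light_mcmc(seed = 6))
  expect_false(identical(f1$draws, f3$draws))
})

test_that("zero records are refused", {
  expect_error(fit_participant(data.frame(game = character(),
                                          context_param = numeric(),
                                          chosen_label = character())),
               "at least one")
})

test_that("ties-only data returns the prior (MCMC and grid)", {
  ctx <- list(ties_context())
  ch <- data.frame(game = "DG", context_param = 999, chosen_label = "a")
  pr <- prior_spec()
  fit <- fit_participant(ch, ctx, pr,
                         mcmc_config(n_chains = 2, n_warmup = 1000,
                                     n_samples = 3000, seed = 3))
  s <- fit$summary
  # prior moments: alpha ~ N(0.8, 1), beta ~ N(0.4, 0.5),
  # lambda ~ half-N(0, 5) with mean 5*sqrt(2/pi), sd 5*sqrt(1-2/pi)
  expect_equal(s$mean[s$param == "alpha"], pr$alpha_mean, tolerance = 0.1)
  expect_equal(s$sd[s$param == "alpha"], pr$alpha_sd, tolerance = 0.1)
  expect_equal(s$mean[s$param == "beta"], pr$beta_mean, tolerance = 0.06)
  expect_equal(s$mean[s$param == "lambda"], 5 * sqrt(2 / pi),
               tolerance = 0.35)
  gp <- grid_posterior(ch, ctx, pr)
  expect_equal(unname(gp$mean["alpha"]), pr$alpha_mean, tolerance = 0.02)
  expect_equal(unname(gp$sd["alpha"]), pr$alpha_sd, tolerance = 0.02)
  expect_equal(unname(gp$mean["lambda"]), 5 * sqrt(2 / pi), tolerance = 0.1)
})

test_that("grid posterior matches a hand-built Bayes update", {
  # single responder decision: accept offer 300 of 1500. beta never enters;
  # its marginal must equal the prior. The (alpha, lambda) posterior is
  # checked against plain 2-D quadrature written here from scratch.
  ctx <- build_ug_responder_contexts()[4]
  expect_equal(ctx[[1]]$context_param, 300)
  ch <- data.frame(game = "UG_RESPONDER", context_param = 300,
                   chosen_label = "accept")
  pr <- prior_spec()
  gp <- grid_posterior(ch, ctx, pr)
  a_grid <- seq(-4, 6, length.out = 801)
  l_grid <- seq(0.005, 20, length.out = 801)
  u_acc <- 0.3 - 0.45 * a_grid              # kJPY: 0.3 - alpha * 0.45
  p_acc <- 1 / (1 + exp(-outer(u_acc, l_grid)))
  w <- p_acc * dnorm(a_grid, pr$alpha_mean, pr$alpha_sd) *
    outer(rep(1, length(a_grid)), dnorm(l_grid, 0, pr$lambda_sd))
  expect_equal(unname(gp$mean["alpha"]),
               sum(a_grid * rowSums(w)) / sum(w), tolerance = 0.02)
  expect_equal(unname(gp$mean["lambda"]),
               sum(l_grid * colSums(w)) / sum(w), tolerance = 0.05)
  expect_equal(unname(gp$mean["beta"]), pr$beta_mean, tolerance = 0.02)
  expect_error(grid_posterior(ch, ctx, pr, alpha_grid = 0.5), "degenerate")
})

test_that("a uniform random chooser pulls lambda towards zero", {
  sched <- game_schedule()
  truth <- data.frame(participant_id = "P1", true_alpha = 0, true_beta = 0,
                      true_lambda = 0)
  ch <- simulate_choices(truth, sched, seed = 9)[, -1]
  fit <- fit_participant(ch, sched, config = light_mcmc(seed = 4))
  prior_mean_lambda <- 5 * sqrt(2 / pi)
  expect_lt(coef(fit)[["lambda"]], prior_mean_lambda / 2)
})

test_that("cohort estimation returns one diagnosed row per participant", {
  cfg <- simulation_config(n_participants = 3, seed = 77)
  study <- generate_study(cfg)
  est <- suppressWarnings(
    estimate_cohort(study$behaviour, game_schedule(),
                    config = light_mcmc(seed = 12)))
  expect_s3_class(est, "ia_cohort")
  expect_equal(nrow(est), 3)
  expect_setequal(est$participant_id, study$truth$participant_id)
  expect_true(all(est$rhat_max >= 0.99))
  expect_true(all(est$alpha_sd > 0 & est$beta_sd > 0 & est$lambda_sd > 0))
  one <- suppressWarnings(
    estimate_cohort(study$behaviour[study$behaviour$participant_id ==
                                      "P0001", ],
                    game_schedule(), config = light_mcmc(seed = 12)))
  expect_equal(nrow(one), 1)
})

test_that("posterior summaries are internally coherent", {
  sched <- game_schedule()
  truth <- data.frame(participant_id = "P1", true_alpha = 1, true_beta = 0.6,
                      true_lambda = 8)
  ch <- simulate_choices(truth, sched, seed = 31)[, -1]
  fit <- fit_participant(ch, sched, config = light_mcmc(seed = 8))
  s <- fit$summary
  expect_true(all(s$q2.5 <= s$mean & s$mean <= s$q97.5))
  expect_true(all(s$rhat >= 0.99))
  expect_true(all(s$ess > 0))
  expect_true(all(fit$draws[, , "lambda"] >= 0))
})
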