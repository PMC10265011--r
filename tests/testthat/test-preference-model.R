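test_that("utility subtracts the active inequity penalty only", {
  expect_equal(fs_utility(500, 500, preference_params(0.9, 0.7, 1)), 500)
  expect_equal(fs_utility(0, 1000, preference_params(0.5, 0.5, 1)), -250)
  expect_equal(fs_utility(1000, 0, preference_params(0.5, 0.2, 1)), 900)
  # generic: exactly one penalty can bite
  set.seed(1)
  for (i in 1:20) {
    x <- runif(1, 0, 2000); y <- runif(1, 0, 2000)
    p <- preference_params(runif(1, -1, 2), runif(1, -1, 2), 1)
    dis <- max((y - x) / 2, 0); adv <- max((x - y) / 2, 0)
    expect_true(dis == 0 || adv == 0)
    expect_equal(fs_utility(x, y, p), x - p$alpha * dis - p$beta * adv)
  }
})

test_that("softmax probabilities are normalized, positive and stable", {
  sched <- game_schedule()
  set.seed(42)
  for (i in 1:200) {
    ctx <- sched[[sample.int(length(sched), 1)]]
    pars <- preference_params(runif(1, -2, 3), runif(1, -2, 3),
                              runif(1, 0, 30))
    p <- choice_probabilities(ctx, pars)
    expect_true(all(p > 0))
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }
  # no overflow at extreme inverse temperature
  p <- choice_probabilities(sched[[1]], preference_params(0.5, 0.5, 700))
  expect_true(all(is.finite(p)))
  expect_equal(sum(p), 1, tolerance = 1e-12)
})

test_that("softmax is invariant to constant utility shifts", {
  base <- iafit:::new_context("DG", 1, c("a", "b", "c"),
                              x = c(100, 400, 900), y = c(100, 400, 900))
  shifted <- iafit:::new_context("DG", 1, c("a", "b", "c"),
                                 x = c(100, 400, 900) + 500,
                                 y = c(100, 400, 900) + 500)
  pars <- preference_params(0.7, 0.3, 6)  # equal splits: U = x, shift = const
  expect_equal(unname(choice_probabilities(base, pars)),
               unname(choice_probabilities(shifted, pars)),
               tolerance = 1e-12)
})

test_that("lambda limits: uniform at 0, degenerate at the maximizer", {
  ctx <- build_dg_contexts(1000)[[1]]
  p0 <- choice_probabilities(ctx, preference_params(1.2, 0.8, 0))
  expect_equal(unname(p0), rep(1 / 11, 11))
  even <- iafit:::new_context("UG_RESPONDER", 750, c("accept", "reject"),
                              x = c(750, 750), y = c(750, 750))
  expect_equal(unname(choice_probabilities(even, preference_params(1, 1, 5))),
               c(0.5, 0.5))
  pars <- lapply(c(0.5, 2, 8, 32, 256), function(l)
    preference_params(0.5, 1.5, l))
  best <- deterministic_choice(ctx, pars[[1]])
  pb <- vapply(pars, function(p) choice_probabilities(ctx, p)[[best]],
               numeric(1))
  expect_true(all(diff(pb) > 0))
  expect_gt(pb[5], 0.999)
})

test_that("responder acceptance is monotone in the offer below the split", {
  pars <- preference_params(0.8, 0, 5)
  resp <- build_ug_responder_contexts()
  offers <- vapply(resp, function(c) c$context_param, numeric(1))
  acc <- vapply(resp, function(c)
    choice_probabilities(c, pars)[["accept"]], numeric(1))
  expect_true(all(diff(acc[offers <= 750]) >= 0))
})

test_that("large-lambda rejection threshold equals 750 alpha/(1+alpha)", {
  resp <- build_ug_responder_contexts()
  offers <- vapply(resp, function(c) c$context_param, numeric(1))
  for (a in c(0.25, 0.5, 1, 2)) {
    thr <- 750 * a / (1 + a)
    acc <- vapply(resp, function(c)
      choice_probabilities(c, preference_params(a, 0, 500))[["accept"]],
      numeric(1))
    expect_true(all(acc[offers > thr + 1] > 0.99))
    expect_true(all(acc[offers < thr - 1] < 0.01))
  }
})

test_that("deterministic choice maximizes utility with stable ties", {
  dg <- build_dg_contexts(1000)[[1]]
  expect_equal(deterministic_choice(dg, preference_params(0.5, 1.5, 1)),
               "500")
  expect_equal(deterministic_choice(dg, preference_params(0, 0, 1)), "0")
  o700 <- build_ug_responder_contexts()[[8]]
  expect_equal(o700$context_param, 700)
  expect_equal(deterministic_choice(o700, preference_params(1, 0, 1)),
               "accept")
  even <- iafit:::new_context("X", 1, c("b", "a"), x = c(10, 10),
                              y = c(10, 10))
  expect_equal(deterministic_choice(even, preference_params(0, 0, 1)), "a")
})

test_that("log-likelihood equals the per-record brute-force sum", {
  sched <- game_schedule()
  expect_equal(choice_loglik(data.frame(game = character(),
                                        context_param = numeric(),
                                        chosen_label = character()),
                             sched, preference_params(1, 1, 5)), 0)
  one <- data.frame(game = "UG_RESPONDER", context_param = 700,
                    chosen_label = "accept")
  expect_equal(choice_loglik(one, sched, preference_params(0, 0, 0)),
               log(0.5))
  truth <- data.frame(participant_id = "P1", true_alpha = 0.7,
                      true_beta = 0.5, true_lambda = 6)
  ch <- simulate_choices(truth, sched, seed = 11)[, -1]
  pars <- preference_params(0.9, 0.2, 4)
  brute <- 0
  for (i in seq_len(nrow(ch))) {
    ctx <- Filter(function(c) c$game == ch$game[i] &&
                    c$context_param == ch$context_param[i], sched)[[1]]
    u <- ctx$options$weight *
      fs_utility(ctx$options$x / 1000, ctx$options$y / 1000, pars)
    pr <- exp(pars$lambda * u) / sum(exp(pars$lambda * u))
    brute <- brute + log(pr[ctx$options$label == ch$chosen_label[i]])
  }
  expect_equal(choice_loglik(ch, sched, pars), brute, tolerance = 1e-10)
  md <- iafit:::choice_model_data(ch, sched)
  expect_equal(iafit:::cpp_loglik(0.9, 0.2, 4, md$x, md$d, md$a, md$ctx,
                                  md$n_contexts, md$chosen),
               brute, tolerance = 1e-10)
  expect_error(choice_loglik(data.frame(game = "DG", context_param = 1000,
                                        chosen_label = "150"), sched, pars),
               "row")
})
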