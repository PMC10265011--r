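test_that("dictator contexts enumerate the endowment grid", {
  ctxs <- build_dg_contexts()
  expect_length(ctxs, 7)
  expect_equal(vapply(ctxs, function(c) c$context_param, numeric(1)),
               c(1000, 300, 400, 600, 700, 1200, 1300))
  # option count is E/100 + 1
  expect_equal(vapply(ctxs, function(c) nrow(c$options), integer(1)),
               c(1000, 300, 400, 600, 700, 1200, 1300) / 100 + 1)
  e1000 <- ctxs[[1]]$options
  expect_equal(e1000[e1000$label == "0", c("x", "y")],
               data.frame(x = 1000, y = 0), ignore_attr = TRUE)
  expect_error(build_dg_contexts(c(1000, 150)), "multiple of 100")
})

test_that("prisoner's dilemma payoffs follow the doubled-transfer rule", {
  expect_equal(pdg_realized_payoffs(200, 500), c(x = 1800, y = 900))
  expect_equal(pdg_realized_payoffs(0, 0), c(x = 1000, y = 1000))
  expect_equal(pdg_realized_payoffs(1000, 1000), c(x = 2000, y = 2000))
  expect_error(pdg_realized_payoffs(150, 500), "grid")
  # swapping contributions swaps payoffs
  for (cs in c(0, 300, 700)) {
    for (co in c(100, 600, 1000)) {
      ab <- pdg_realized_payoffs(cs, co)
      ba <- pdg_realized_payoffs(co, cs)
      expect_equal(unname(ab), unname(rev(ba)))
    }
  }
  ctx <- build_pdg_context(belief_config(pdg_opponent_contribution = 500))
  expect_equal(nrow(ctx$options), 11)
  expect_equal(unlist(ctx$options[ctx$options$label == "500", c("x", "y")]),
               c(x = 1500, y = 1500))
  expect_equal(unlist(ctx$options[ctx$options$label == "200", c("x", "y")]),
               c(x = 1800, y = 900))
})

test_that("public goods context splits the doubled pool equally", {
  b0 <- build_pgg_context(belief_config(pgg_other_contribution = 0))
  expect_equal(unlist(b0$options[b0$options$label == "0", c("x", "y")]),
               c(x = 1000, y = 1000))
  expect_equal(unlist(b0$options[b0$options$label == "1000", c("x", "y")]),
               c(x = 200, y = 1200))
  # identical contributions equalize self and representative-other payoffs
  for (b in c(0, 300, 1000)) {
    ctx <- build_pgg_context(belief_config(pgg_other_contribution = b))
    row <- ctx$options[ctx$options$label == as.character(b), ]
    expect_equal(row$x, row$y)
  }
  expect_error(build_pgg_context(group_size = 1), "group_size")
})

test_that("trust game contexts implement tripled transfer and returns", {
  tr <- build_tg_truster_context(
    belief_config(tg_expected_return_fraction = 1 / 3))
  expect_equal(unlist(tr$options[tr$options$label == "900", c("x", "y")]),
               c(x = 1000, y = 1800))
  expect_equal(unlist(tr$options[tr$options$label == "0", c("x", "y")]),
               c(x = 1000, y = 0))
  full <- build_tg_truster_context(
    belief_config(tg_expected_return_fraction = 1))
  expect_equal(unlist(full$options[full$options$label == "1000",
                                   c("x", "y")]),
               c(x = 3000, y = 0))
  te <- build_tg_trustee_contexts()
  expect_length(te, 10)
  expect_true(all(vapply(te, function(c) nrow(c$options), integer(1)) == 11))
  t1000 <- te[[10]]$options
  expect_equal(unlist(t1000[t1000$label == "0.5", c("x", "y")]),
               c(x = 1500, y = 1500))
  t100 <- te[[1]]$options
  expect_equal(unlist(t100[t100$label == "0", c("x", "y")]),
               c(x = 300, y = 900))
  expect_true(all(vapply(te, function(c) {
    c$options$x[c$options$label == "1"] == 0
  }, logical(1))))
})

test_that("ultimatum contexts cover 16 offers with veto payoffs", {
  prop <- build_ug_proposer_context()
  expect_equal(nrow(prop$options), 16)
  # the JPY 100 grid over 1500 has no exact even split; check a grid offer
  expect_equal(unlist(prop$options[prop$options$label == "700",
                                   c("x", "y")]),
               c(x = 800, y = 700))
  expect_false("750" %in% prop$options$label)
  expect_error(
    build_ug_proposer_context(
      structure(list(ug_proposer_mode = "rejection_belief",
                     ug_proposer_rejection_params = NULL),
                class = "ia_beliefs")),
    "rejection")
  resp <- build_ug_responder_contexts()
  expect_length(resp, 16)
  o0 <- resp[[1]]$options
  # accepting a zero offer leaves the proposer the whole endowment; only the
  # responder's own payoff coincides with rejection
  expect_equal(unlist(o0[o0$label == "accept", c("x", "y")]),
               c(x = 0, y = 1500))
  expect_true(all(vapply(resp, function(c) {
    all(unlist(c$options[c$options$label == "reject", c("x", "y")]) == 0)
  }, logical(1))))
})

test_that("proposer rejection-belief mode attaches acceptance weights", {
  bel <- belief_config(ug_proposer_mode = "rejection_belief",
                       ug_proposer_rejection_params =
                         preference_params(1, 0, 10))
  ctx <- build_ug_proposer_context(bel)
  w <- ctx$options$weight
  expect_true(all(w > 0 & w <= 1))
  expect_true(all(diff(w[1:8]) > 0))  # acceptance rises with low offers
})

test_that("full schedule has 37 contexts and round-trips through CSV", {
  sched <- game_schedule()
  expect_length(sched, 37)
  games <- vapply(sched, function(c) c$game, "")
  expect_equal(as.integer(table(games)[c("DG", "PDG", "PGG", "TG_TRUSTER",
                                         "TG_TRUSTEE", "UG_PROPOSER",
                                         "UG_RESPONDER")]),
               c(7L, 1L, 1L, 1L, 10L, 1L, 16L))
  path <- tempfile(fileext = ".csv")
  write_contexts_csv(sched, path)
  back <- read_contexts_csv(path)
  expect_equal(contexts_to_df(back), contexts_to_df(sched))
})

test_that("every allocation is reproducible from its closed-form rule", {
  sched <- game_schedule()
  for (ctx in sched) {
    opt <- ctx$options
    cp <- ctx$context_param
    recomputed <- switch(ctx$game,
      DG = cbind(cp - as.numeric(opt$label), as.numeric(opt$label)),
      PDG = cbind(1000 - as.numeric(opt$label) + 2 * 500,
                  1000 - 500 + 2 * as.numeric(opt$label)),
      PGG = {
        cc <- as.numeric(opt$label)
        s <- 0.2 * (cc + 9 * 500)
        cbind(1000 - cc + s, 1000 - 500 + s)
      },
      TG_TRUSTER = {
        t <- as.numeric(opt$label)
        cbind(1000 - t + t, 2 * t)  # return fraction 1/3 of 3t
      },
      TG_TRUSTEE = {
        rho <- as.numeric(opt$label)
        cbind(3 * cp * (1 - rho), 1000 - cp + 3 * cp * rho)
      },
      UG_PROPOSER = cbind(1500 - as.numeric(opt$label),
                          as.numeric(opt$label)),
      UG_RESPONDER = cbind(c(cp, 0), c(1500 - cp, 0)))
    expect_equal(cbind(opt$x, opt$y), recomputed, ignore_attr = TRUE)
  }
})
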