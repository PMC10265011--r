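# Decision-context construction for the five economic games.
#
# Every game is reduced to a set of decision contexts: an ordered list of
# labelled options, each carrying the (self, other) payoff allocation it
# implies. Payoffs are stored in JPY; the likelihood rescales to kJPY
# internally (see `payoff_scale`).

#' Payoff scale used inside the choice model
#'
#' All payoffs are stored in JPY in contexts and data files, and divided by
#' this constant (1000, i.e. expressed in kJPY) before entering the utility
#' function, so that the softmax inverse temperature lambda is of order one
#' and comparable across games.
#'
#' @export
payoff_scale <- 1000

#' Beliefs about co-players in simultaneous-move games
#'
#' In the dictator game, trust-game trustee role and ultimatum-game responder
#' role the participant's payoff consequences are fully determined by their
#' own choice. In the prisoner's dilemma, public goods game, trust-game
#' truster role and ultimatum-game proposer role they also depend on what the
#' co-player does. The choice model needs a definite allocation per option,
#' so a belief about the co-player is made explicit and shared between the
#' forward simulator and the fitted likelihood.
#'
#' Defaults are neutral midpoints of the contribution grids (JPY 500) and the
#' break-even expected return fraction 1/3 for the truster (at which
#' transferring is payoff-neutral). The proposer defaults to
#' `"pure_distribution"`: offers are treated as unilateral allocations,
#' ignoring the possibility of rejection. In `"rejection_belief"` mode each
#' offer instead carries the acceptance probability implied by a softmax
#' responder with preferences `ug_proposer_rejection_params`, and the
#' likelihood uses the expected utility of the offer.
#'
#' @param pdg_opponent_contribution assumed opponent contribution in the
#'   prisoner's dilemma, JPY in \[0, 1000\].
#' @param pgg_other_contribution assumed contribution of each other group
#'   member in the public goods game, JPY in \[0, 1000\].
#' @param tg_expected_return_fraction expected fraction of the tripled
#'   transfer returned by the trustee, in \[0, 1\].
#' @param ug_proposer_mode `"pure_distribution"` or `"rejection_belief"`.
#' @param ug_proposer_rejection_params [preference_params()] of the believed
#'   responder; required in `"rejection_belief"` mode.
#' @return An object of class `"ia_beliefs"`.
#' @export
belief_config <- function(pdg_opponent_contribution = 500,
                          pgg_other_contribution = 500,
                          tg_expected_return_fraction = 1 / 3,
                          ug_proposer_mode = c("pure_distribution",
                                               "rejection_belief"),
                          ug_proposer_rejection_params = NULL) {
  ug_proposer_mode <- match.arg(ug_proposer_mode)
  if (pdg_opponent_contribution < 0 || pdg_opponent_contribution > 1000)
    stop("pdg_opponent_contribution must be in [0, 1000]")
  if (pgg_other_contribution < 0 || pgg_other_contribution > 1000)
    stop("pgg_other_contribution must be in [0, 1000]")
  if (tg_expected_return_fraction < 0 || tg_expected_return_fraction > 1)
    stop("tg_expected_return_fraction must be in [0, 1]")
  if (ug_proposer_mode == "rejection_belief" &&
      !inherits(ug_proposer_rejection_params, "ia_params"))
    stop("rejection_belief mode requires ug_proposer_rejection_params ",
         "(a preference_params object)")
  structure(list(pdg_opponent_contribution = pdg_opponent_contribution,
                 pgg_other_contribution = pgg_other_contribution,
                 tg_expected_return_fraction = tg_expected_return_fraction,
                 ug_proposer_mode = ug_proposer_mode,
                 ug_proposer_rejection_params = ug_proposer_rejection_params),
            class = "ia_beliefs")
}

#' Construct a payoff allocation
#'
#' @param x self payoff (JPY, finite, non-negative).
#' @param y other payoff (JPY, finite, non-negative).
#' @return Named numeric vector `c(x = , y = )`.
#' @export
allocation <- function(x, y) {
  if (!all(is.finite(x)) || !all(is.finite(y)) || any(x < 0) || any(y < 0))
    stop("allocation payoffs must be finite and non-negative")
  c(x = unname(x), y = unname(y))
}

new_context <- function(game, context_param, labels, x, y, weight = 1) {
  labels <- as.character(labels)
  stopifnot(length(labels) >= 2L, !anyDuplicated(labels),
            length(x) == length(labels), length(y) == length(labels))
  if (!all(is.finite(x)) || !all(is.finite(y)) || any(x < 0) || any(y < 0))
    stop("context option payoffs must be finite and non-negative")
  options <- data.frame(label = labels, x = x, y = y,
                        weight = rep_len(weight, length(labels)),
                        stringsAsFactors = FALSE)
  structure(list(game = game, context_param = context_param,
                 options = options),
            class = "ia_context")
}

#' @export
print.ia_context <- function(x, ...) {
  cat(sprintf("<ia_context> %s (param = %s), %d options\n",
              x$game, format(x$context_param), nrow(x$options)))
  print(x$options, row.names = FALSE)
  invisible(x)
}

context_key <- function(game, context_param) {
  paste0(game, ":", format(context_param, trim = TRUE))
}

jpy_grid <- function(endowment) seq(0L, endowment, by = 100L)

check_grid <- function(value, endowment, what) {
  if (any(value < 0 | value > endowment | value %% 100 != 0))
    stop(sprintf("%s must lie on the JPY {0, 100, ..., %d} grid", what,
                 endowment))
  invisible(value)
}

#' Dictator-game contexts
#'
#' One context per endowment; the dictator gives `a` of the endowment `E` to
#' the recipient in JPY 100 increments, keeping `E - a`. The recipient holds
#' no own endowment.
#'
#' @param endowments vector of endowments, each a positive multiple of 100
#'   JPY. The default is the seven-endowment schedule JPY 1000, 300, 400,
#'   600, 700, 1200, 1300.
#' @return List of `"ia_context"` objects.
#' @export
build_dg_contexts <- function(endowments = c(1000, 300, 400, 600, 700,
                                             1200, 1300)) {
  if (any(endowments <= 0 | endowments %% 100 != 0))
    stop("every endowment must be a positive multiple of 100 JPY")
  lapply(endowments, function(E) {
    a <- jpy_grid(E)
    new_context("DG", E, labels = a, x = E - a, y = a)
  })
}

#' Realized prisoner's dilemma payoffs
#'
#' Each player keeps the unprovided part of the endowment and receives the
#' partner's contribution multiplied (doubled by default). For example
#' contributions (200, 500) give the first player JPY 800 + 2 x 500 = 1800
#' and the second JPY 500 + 2 x 200 = 900.
#'
#' @param c_self,c_other own and partner contribution, on the JPY 100 grid.
#' @param endowment endowment per player (JPY 1000).
#' @param multiplier multiplier applied to the received transfer (2).
#' @return [allocation()] `(x, y)` for (self, other).
#' @export
pdg_realized_payoffs <- function(c_self, c_other, endowment = 1000,
                                 multiplier = 2) {
  check_grid(c_self, endowment, "c_self")
  check_grid(c_other, endowment, "c_other")
  allocation(endowment - c_self + multiplier * c_other,
             endowment - c_other + multiplier * c_self)
}

#' Prisoner's dilemma decision context
#'
#' Options are own contributions on the JPY 100 grid; allocations are the
#' realized payoffs against the believed opponent contribution.
#'
#' @param beliefs a [belief_config()].
#' @param endowment endowment per player (JPY 1000).
#' @param multiplier transfer multiplier (2).
#' @return An `"ia_context"` with 11 options.
#' @export
build_pdg_context <- function(beliefs = belief_config(), endowment = 1000,
                              multiplier = 2) {
  b <- beliefs$pdg_opponent_contribution
  cc <- jpy_grid(endowment)
  new_context("PDG", endowment, labels = cc,
              x = endowment - cc + multiplier * b,
              y = endowment - b + multiplier * cc)
}

#' Public goods game decision context
#'
#' The pool (own contribution plus the assumed identical contribution of each
#' of the `group_size - 1` others) is multiplied and split equally. Inequity
#' is evaluated against a single representative other, assumed identical to
#' the rest of the group.
#'
#' @param beliefs a [belief_config()].
#' @param group_size number of group members (>= 2; instructions assumed 10).
#' @param multiplier pool multiplier (2).
#' @return An `"ia_context"` with 11 options.
#' @export
build_pgg_context <- function(beliefs = belief_config(), group_size = 10,
                              multiplier = 2) {
  if (group_size < 2) stop("group_size must be >= 2")
  b <- beliefs$pgg_other_contribution
  cc <- jpy_grid(1000)
  s <- (multiplier / group_size) * (cc + (group_size - 1) * b)
  new_context("PGG", 1000, labels = cc,
              x = 1000 - cc + s, y = 1000 - b + s)
}

#' Trust game truster context
#'
#' The truster transfers `t`, the trustee receives `3 t` and is believed to
#' return the fraction `tg_expected_return_fraction` of it.
#'
#' @param beliefs a [belief_config()].
#' @return An `"ia_context"` with 11 options.
#' @export
build_tg_truster_context <- function(beliefs = belief_config()) {
  rho <- beliefs$tg_expected_return_fraction
  t <- jpy_grid(1000)
  new_context("TG_TRUSTER", 1000, labels = t,
              x = 1000 - t + 3 * t * rho, y = 3 * t * (1 - rho))
}

#' Trust game trustee contexts (strategy method)
#'
#' One context per possible truster transfer t in JPY 100 to 1000; the
#' trustee chooses the fraction of the tripled amount to return in 10%
#' increments. The trustee holds no own endowment: their payoff is the kept
#' part of `3 t`; the truster's payoff includes the kept `1000 - t`.
#'
#' @return List of 10 `"ia_context"` objects with 11 options each.
#' @export
build_tg_trustee_contexts <- function() {
  lapply(seq(100L, 1000L, by = 100L), function(t) {
    rho <- (0:10) / 10
    new_context("TG_TRUSTEE", t, labels = rho,
                x = 3 * t * (1 - rho), y = 1000 - t + 3 * t * rho)
  })
}

#' Ultimatum game proposer context
#'
#' Offers `o` on the JPY 100 grid up to the endowment (JPY 1500). In
#' `"pure_distribution"` mode an offer is treated as a unilateral allocation
#' `(1500 - o, o)`. In `"rejection_belief"` mode each option additionally
#' carries the acceptance probability of a softmax responder with the
#' configured preferences, and the likelihood uses the expected utility
#' `p_accept * U(1500 - o, o)` (the rejection outcome (0, 0) has zero
#' utility).
#'
#' @param beliefs a [belief_config()].
#' @param endowment proposer endowment (JPY 1500).
#' @return An `"ia_context"` with 16 options.
#' @export
build_ug_proposer_context <- function(beliefs = belief_config(),
                                      endowment = 1500) {
  o <- jpy_grid(endowment)
  w <- 1
  if (beliefs$ug_proposer_mode == "rejection_belief") {
    pars <- beliefs$ug_proposer_rejection_params
    if (is.null(pars))
      stop("rejection_belief mode requires ug_proposer_rejection_params")
    w <- vapply(build_ug_responder_contexts(endowment), function(ctx) {
      unname(choice_probabilities(ctx, pars)["accept"])
    }, numeric(1))
  }
  new_context("UG_PROPOSER", endowment, labels = o,
              x = endowment - o, y = o, weight = w)
}

#' Ultimatum game responder contexts (strategy method)
#'
#' One binary accept/reject context per offer `o` on the JPY 100 grid from 0
#' to the endowment: accepting yields `(o, 1500 - o)`, rejecting `(0, 0)`.
#'
#' @param endowment proposer endowment (JPY 1500), giving 16 offers.
#' @return List of 16 `"ia_context"` objects with 2 options each.
#' @export
build_ug_responder_contexts <- function(endowment = 1500) {
  lapply(jpy_grid(endowment), function(o) {
    new_context("UG_RESPONDER", o, labels = c("accept", "reject"),
                x = c(o, 0), y = c(endowment - o, 0))
  })
}

#' Full decision schedule of the five-game study
#'
#' The complete per-participant schedule: 7 dictator-game contexts, 1
#' prisoner's dilemma, 1 public goods game, 1 trust-game truster, 10
#' trust-game trustee (strategy method) and 1 ultimatum-game proposer plus
#' 16 responder contexts — 37 decisions in total.
#'
#' @param beliefs a [belief_config()] shared by the simulator and the fit.
#' @param dg_endowments endowment schedule for the dictator game.
#' @return List of 37 `"ia_context"` objects.
#' @export
game_schedule <- function(beliefs = belief_config(),
                          dg_endowments = c(1000, 300, 400, 600, 700,
                                            1200, 1300)) {
  c(build_dg_contexts(dg_endowments),
    list(build_pdg_context(beliefs),
         build_pgg_context(beliefs),
         build_tg_truster_context(beliefs)),
    build_tg_trustee_contexts(),
    list(build_ug_proposer_context(beliefs)),
    build_ug_responder_contexts())
}

#' Flatten contexts to a long-format data frame
#'
#' @param contexts list of `"ia_context"` objects.
#' @return Data frame with columns game, context_param, option_label, x, y,
#'   weight (one row per option).
#' @export
contexts_to_df <- function(contexts) {
  do.call(rbind, lapply(contexts, function(ctx) {
    data.frame(game = ctx$game, context_param = ctx$context_param,
               option_label = ctx$options$label, x = ctx$options$x,
               y = ctx$options$y, weight = ctx$options$weight,
               stringsAsFactors = FALSE)
  }))
}

#' Rebuild contexts from a long-format data frame
#'
#' Inverse of [contexts_to_df()] up to column order; option order within each
#' context and context order follow first appearance in the data frame.
#'
#' @param df data frame with columns game, context_param, option_label, x, y
#'   and optionally weight.
#' @return List of `"ia_context"` objects.
#' @export
contexts_from_df <- function(df) {
  need <- c("game", "context_param", "option_label", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing context columns: ", paste(miss, collapse = ", "))
  if (is.null(df$weight)) df$weight <- 1
  key <- context_key(df$game, df$context_param)
  lapply(unique(key), function(k) {
    rows <- df[key == k, , drop = FALSE]
    new_context(rows$game[1], rows$context_param[1], rows$option_label,
                rows$x, rows$y, rows$weight)
  })
}

#' Write / read a context schedule as CSV
#'
#' @param contexts list of contexts.
#' @param path file path.
#' @return `read_contexts_csv` returns the context list.
#' @export
write_contexts_csv <- function(contexts, path) {
  utils::write.csv(contexts_to_df(contexts), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_contexts_csv
#' @export
read_contexts_csv <- function(path) {
  contexts_from_df(utils::read.csv(path, stringsAsFactors = FALSE,
                                   colClasses = c(option_label = "character")))
}
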