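# Inequity-aversion utility, softmax choice rule and joint log-likelihood.

#' Inequity-aversion preference parameters
#'
#' `alpha` (disadvantageous inequity aversion, DIA) weights the deviation
#' from the equal split when the other earns more; `beta` (advantageous
#' inequity aversion, AIA) weights it when the self earns more; `lambda` is
#' the softmax inverse temperature (0 = random choice, large = deterministic
#' utility maximization), expressed per kJPY of utility. Neither sign
#' constraints nor the classic `beta <= alpha`, `beta < 1` restrictions are
#' imposed on the likelihood; any regularization lives in the priors.
#'
#' @param alpha,beta finite reals.
#' @param lambda non-negative real (kJPY^-1).
#' @return An object of class `"ia_params"`.
#' @export
preference_params <- function(alpha, beta, lambda) {
  stopifnot(is.finite(alpha), is.finite(beta), is.finite(lambda))
  if (lambda < 0) stop("lambda must be non-negative")
  structure(list(alpha = alpha, beta = beta, lambda = lambda),
            class = "ia_params")
}

#' @export
print.ia_params <- function(x, ...) {
  cat(sprintf("<ia_params> alpha = %.4g, beta = %.4g, lambda = %.4g\n",
              x$alpha, x$beta, x$lambda))
  invisible(x)
}

#' Inequity-aversion utility of an allocation
#'
#' `U(x, y) = x - alpha * max((x + y)/2 - x, 0) - beta * max(x - (x + y)/2, 0)`:
#' own payoff discounted by the alpha-weighted shortfall from the equal split
#' when the other earns more, and by the beta-weighted excess when the self
#' earns more. At most one penalty term is non-zero; utility is in the same
#' units as the payoffs supplied.
#'
#' @param x,y self and other payoffs (vectorized).
#' @param params a [preference_params()].
#' @return Numeric utility vector.
#' @export
fs_utility <- function(x, y, params) {
  x - params$alpha * pmax((y - x) / 2, 0) - params$beta * pmax((x - y) / 2, 0)
}

option_utilities <- function(context, params, scale = payoff_scale) {
  opt <- context$options
  opt$weight * fs_utility(opt$x / scale, opt$y / scale, params)
}

#' Softmax choice probabilities in a context
#'
#' `P(option) = exp(lambda * U) / sum(exp(lambda * U))` over the context's
#' option set, computed on the kJPY utility scale with max-subtraction so no
#' overflow occurs for extreme `lambda * U`.
#'
#' @param context an `"ia_context"`.
#' @param params a [preference_params()].
#' @param scale payoff rescaling divisor (default [payoff_scale]).
#' @return Named probability vector (names = option labels) summing to 1.
#' @export
choice_probabilities <- function(context, params, scale = payoff_scale) {
  v <- params$lambda * option_utilities(context, params, scale)
  v <- v - max(v)
  p <- exp(v)
  p <- p / sum(p)
  names(p) <- context$options$label
  p
}

#' Utility-maximizing option of a context
#'
#' The `lambda -> Inf` limit of the softmax rule; ties (within 1e-12 kJPY)
#' are broken by the lexicographically lowest option label, for
#' reproducibility.
#'
#' @inheritParams choice_probabilities
#' @return The chosen option label (character scalar).
#' @export
deterministic_choice <- function(context, params, scale = payoff_scale) {
  u <- option_utilities(context, params, scale)
  top <- context$options$label[u >= max(u) - 1e-12]
  sort(top)[1]
}

#' Joint log-likelihood of a participant's choices
#'
#' Sums the log softmax probability of each chosen option over all decisions,
#' treating decisions as conditionally independent given the preference
#' parameters. Choices are matched to contexts by (game, context_param).
#'
#' @param choices data frame with columns game, context_param, chosen_label
#'   (one row per decision).
#' @param contexts list of `"ia_context"` objects, e.g. [game_schedule()].
#' @param params a [preference_params()].
#' @param scale payoff rescaling divisor.
#' @return Log-likelihood (0 for an empty choice table).
#' @export
choice_loglik <- function(choices, contexts, params, scale = payoff_scale) {
  if (nrow(choices) == 0) return(0)
  idx <- match_choices(choices, contexts)
  ll <- 0
  for (i in seq_len(nrow(choices))) {
    p <- choice_probabilities(contexts[[idx$context[i]]], params, scale)
    ll <- ll + log(p[[idx$option_name[i]]])
  }
  ll
}

# Resolve each choice row to a context index and chosen label; errors carry
# row numbers so malformed data files are diagnosable.
match_choices <- function(choices, contexts) {
  need <- c("game", "context_param", "chosen_label")
  miss <- setdiff(need, names(choices))
  if (length(miss))
    stop("missing choice columns: ", paste(miss, collapse = ", "))
  keys <- vapply(contexts, function(ctx) context_key(ctx$game,
                                                     ctx$context_param), "")
  ckey <- context_key(choices$game, choices$context_param)
  cidx <- match(ckey, keys)
  if (anyNA(cidx))
    stop("choices reference unknown contexts at row(s): ",
         paste(which(is.na(cidx)), collapse = ", "))
  lab <- as.character(choices$chosen_label)
  bad <- !mapply(function(i, l) l %in% contexts[[i]]$options$label, cidx, lab)
  if (any(bad))
    stop("chosen_label not in the context's option set at row(s): ",
         paste(which(bad), collapse = ", "))
  list(context = cidx, option_name = lab)
}

# Flatten a context list into the arrays the compiled likelihood consumes:
# per-option (weighted, kJPY) own payoff and the two inequity distances, a
# 0-based context index, and per-context option offsets.
likelihood_data <- function(contexts, scale = payoff_scale) {
  xs <- ds <- as <- numeric(0)
  ctx <- integer(0)
  offset <- integer(length(contexts))
  labels <- vector("list", length(contexts))
  for (i in seq_along(contexts)) {
    opt <- contexts[[i]]$options
    offset[i] <- length(xs)
    xs <- c(xs, opt$weight * opt$x / scale)
    ds <- c(ds, opt$weight * pmax((opt$y - opt$x) / 2, 0) / scale)
    as <- c(as, opt$weight * pmax((opt$x - opt$y) / 2, 0) / scale)
    ctx <- c(ctx, rep.int(i - 1L, nrow(opt)))
    labels[[i]] <- opt$label
  }
  keys <- vapply(contexts, function(ctx) context_key(ctx$game,
                                                     ctx$context_param), "")
  list(x = xs, d = ds, a = as, ctx = ctx, offset = offset,
       labels = labels, keys = keys, n_contexts = length(contexts))
}

# Per-decision model data: one context instance per choice row (so repeated
# or partial schedules are handled uniformly), plus the 0-based flat index of
# each chosen option.
choice_model_data <- function(choices, contexts, scale = payoff_scale) {
  idx <- match_choices(choices, contexts)
  inst <- contexts[idx$context]
  ld <- likelihood_data(inst, scale)
  chosen <- vapply(seq_along(inst), function(i) {
    ld$offset[i] + match(idx$option_name[i], ld$labels[[i]]) - 1L
  }, integer(1))
  c(ld, list(chosen = chosen))
}
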