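# S3 methods for "ia_fit" objects.

#' @export
print.ia_fit <- function(x, ...) {
  cat(sprintf("Inequity-aversion fit: %d decisions, %d chains x %d draws\n",
              x$n_decisions, x$config$n_chains, x$config$n_samples))
  s <- x$summary
  cat(sprintf("  alpha (DIA) %7.3f (sd %.3f)\n", s$mean[1], s$sd[1]))
  cat(sprintf("  beta  (AIA) %7.3f (sd %.3f)\n", s$mean[2], s$sd[2]))
  cat(sprintf("  lambda      %7.3f (sd %.3f)  [kJPY^-1]\n",
              s$mean[3], s$sd[3]))
  cat(sprintf("  max R-hat %.3f, min ESS %.0f%s\n", max(s$rhat), min(s$ess),
              if (x$converged) "" else "  ** NOT CONVERGED **"))
  invisible(x)
}

#' Posterior summary of an inequity-aversion fit
#'
#' @param object an `"ia_fit"`.
#' @param ... unused.
#' @return Data frame with posterior mean, sd, central 95% interval,
#'   split-chain R-hat and effective sample size per parameter, of class
#'   `"summary.ia_fit"`.
#' @export
summary.ia_fit <- function(object, ...) {
  out <- object$summary
  attr(out, "accept_rate") <- object$accept_rate
  attr(out, "converged") <- object$converged
  attr(out, "seed") <- object$config$seed
  class(out) <- c("summary.ia_fit", "data.frame")
  out
}

#' @export
print.summary.ia_fit <- function(x, ...) {
  print.data.frame(x, row.names = FALSE, digits = 4)
  cat(sprintf("converged: %s (seed %d, mean acceptance %.2f)\n",
              attr(x, "converged"), attr(x, "seed"),
              mean(attr(x, "accept_rate"))))
  invisible(x)
}

#' @export
coef.ia_fit <- function(object, ...) {
  stats::setNames(object$summary$mean, ia_param_names)
}

point_params <- function(object) {
  cf <- coef(object)
  preference_params(cf[["alpha"]], cf[["beta"]], cf[["lambda"]])
}

#' Predicted choice probabilities at the posterior mean
#'
#' @param object an `"ia_fit"`.
#' @param contexts contexts to predict for (default: those used in fitting).
#' @param ... unused.
#' @return Data frame with one row per option: game, context_param, label
#'   and predicted probability.
#' @export
predict.ia_fit <- function(object, contexts = object$contexts, ...) {
  pars <- point_params(object)
  do.call(rbind, lapply(contexts, function(ctx) {
    data.frame(game = ctx$game, context_param = ctx$context_param,
               option_label = ctx$options$label,
               prob = unname(choice_probabilities(ctx, pars)),
               stringsAsFactors = FALSE)
  }))
}

#' Simulate choice tables from a fitted participant
#'
#' Draws whole decision schedules from the softmax model at the posterior
#' mean parameters (a posterior-predictive check at the point estimate).
#'
#' @param object an `"ia_fit"`.
#' @param nsim number of replicate schedules.
#' @param seed optional seed.
#' @param ... unused.
#' @return List of `nsim` choice data frames (game, context_param,
#'   chosen_label).
#' @export
simulate.ia_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  pars <- point_params(object)
  lapply(seq_len(nsim), function(s) {
    do.call(rbind, lapply(object$contexts, function(ctx) {
      p <- choice_probabilities(ctx, pars)
      data.frame(game = ctx$game, context_param = ctx$context_param,
                 chosen_label = sample(names(p), 1, prob = p),
                 stringsAsFactors = FALSE)
    }))
  })
}

#' @export
logLik.ia_fit <- function(object, ...) {
  val <- choice_loglik(object$choices, object$contexts, point_params(object))
  structure(val, df = 3L, nobs = object$n_decisions, class = "logLik")
}

#' Per-decision surprisal residuals
#'
#' Returns `-log P(chosen option)` at the posterior mean for every decision:
#' 0 for a perfectly predicted choice, large for choices the fitted model
#' finds improbable.
#'
#' @param object an `"ia_fit"`.
#' @param ... unused.
#' @return Numeric vector, one element per decision, named game:param.
#' @export
residuals.ia_fit <- function(object, ...) {
  pars <- point_params(object)
  idx <- match_choices(object$choices, object$contexts)
  out <- vapply(seq_along(idx$context), function(i) {
    p <- choice_probabilities(object$contexts[[idx$context[i]]], pars)
    -log(p[[idx$option_name[i]]])
  }, numeric(1))
  names(out) <- vapply(idx$context, function(ci) {
    context_key(object$contexts[[ci]]$game,
                object$contexts[[ci]]$context_param)
  }, "")
  out
}

#' Trace and density plots for an inequity-aversion fit
#'
#' @param x an `"ia_fit"`.
#' @param ... passed to [graphics::matplot()] for the traces.
#' @export
plot.ia_fit <- function(x, ...) {
  old <- graphics::par(mfrow = c(3, 2), mar = c(3, 4, 2, 1))
  on.exit(graphics::par(old))
  for (k in 1:3) {
    mat <- x$draws[, , k, drop = TRUE]
    if (is.null(dim(mat))) mat <- matrix(mat, ncol = 1)
    graphics::matplot(mat, type = "l", lty = 1, xlab = "",
                      ylab = ia_param_names[k],
                      main = paste("trace:", ia_param_names[k]), ...)
    d <- stats::density(as.vector(mat))
    graphics::plot(d, main = paste("posterior:", ia_param_names[k]),
                   xlab = "")
  }
  invisible(x)
}
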