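# Cohort-level estimation: one Bayesian fit per participant.

#' Estimate inequity-aversion parameters for a whole cohort
#'
#' Splits a behaviour table by participant, fits each with
#' [fit_participant()], and collects point estimates (posterior means),
#' posterior standard deviations and convergence diagnostics. Non-converged
#' participants are flagged and reported, never dropped. Per-participant
#' seeds are derived deterministically from `config$seed`, so the cohort fit
#' is reproducible and participants can be re-fit independently.
#'
#' @param behaviour data frame with columns participant_id, game,
#'   context_param, chosen_label.
#' @param contexts decision contexts shared by all participants
#'   (default [game_schedule()]).
#' @param priors a [prior_spec()].
#' @param config an [mcmc_config()]; its seed is the cohort master seed.
#' @param verbose print a progress line per 50 participants.
#' @return Data frame of class `"ia_cohort"`: participant_id, alpha_mean,
#'   alpha_sd, beta_mean, beta_sd, lambda_mean, lambda_sd, rhat_max,
#'   ess_min, converged.
#' @export
estimate_cohort <- function(behaviour, contexts = game_schedule(),
                            priors = prior_spec(), config = mcmc_config(),
                            verbose = FALSE) {
  if (!"participant_id" %in% names(behaviour))
    stop("behaviour table must have a participant_id column")
  ids <- unique(behaviour$participant_id)
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, length(ids))
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    sub <- behaviour[behaviour$participant_id == ids[i], , drop = FALSE]
    cfg <- config
    cfg$seed <- seeds[i]
    fit <- fit_participant(sub, contexts, priors, cfg)
    s <- fit$summary
    rows[[i]] <- data.frame(
      participant_id = ids[i],
      alpha_mean = s$mean[1], alpha_sd = s$sd[1],
      beta_mean = s$mean[2], beta_sd = s$sd[2],
      lambda_mean = s$mean[3], lambda_sd = s$sd[3],
      rhat_max = max(s$rhat), ess_min = min(s$ess),
      converged = fit$converged, stringsAsFactors = FALSE)
    if (verbose && i %% 50 == 0)
      message(sprintf("  fitted %d / %d participants", i, length(ids)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  n_bad <- sum(!out$converged)
  if (n_bad > 0)
    warning(sprintf("%d of %d participants flagged non-converged", n_bad,
                    nrow(out)))
  class(out) <- c("ia_cohort", "data.frame")
  out
}

#' @export
print.ia_cohort <- function(x, ...) {
  cat(sprintf("<ia_cohort> %d participants (%d converged)\n", nrow(x),
              sum(x$converged)))
  cat(sprintf("  alpha (DIA): mean %.3f sd %.3f | beta (AIA): mean %.3f sd %.3f | lambda: mean %.3f\n",
              mean(x$alpha_mean), stats::sd(x$alpha_mean),
              mean(x$beta_mean), stats::sd(x$beta_mean),
              mean(x$lambda_mean)))
  print.data.frame(utils::head(as.data.frame(x), 6), row.names = FALSE,
                   digits = 3)
  if (nrow(x) > 6) cat(sprintf("  ... %d more rows\n", nrow(x) - 6))
  invisible(x)
}

#' Write / read a cohort estimates table as CSV
#'
#' @param estimates an `"ia_cohort"` data frame.
#' @param path file path.
#' @export
write_estimates_csv <- function(estimates, path) {
  utils::write.csv(as.data.frame(estimates), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_estimates_csv
#' @export
read_estimates_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("ia_cohort", "data.frame")
  out
}
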