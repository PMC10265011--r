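# Synthetic-study generator: genotypes under Hardy-Weinberg equilibrium,
# ages, preference parameters with injectable genotype/age effects, and game
# choices drawn from the softmax forward model.

#' Synthetic-study configuration
#'
#' Defaults mirror the design of the genotyped five-game cohort: n = 420
#' participants, allele frequencies chosen so expected genotype proportions
#' match the observed ones (OXTR A/G with G ~ 0.36, RS3 S ~ 0.52 with the
#' 334 bp allele making up ~0.42 of L alleles, OPRM1 A/G with G ~ 0.48),
#' ages ~ Normal(41, 10.5) truncated to \[20, 70\], and truth distributions
#' alpha ~ Normal(0.6, 0.4) truncated to \[-0.5, 3\], beta ~ Normal(0.4,
#' 0.3) truncated to \[-0.5, 2\], lambda ~ LogNormal(log 5, 0.4) on the kJPY
#' scale. Default age slopes reproduce the observed age-preference
#' correlations (r ~ 0.13 with DIA, r ~ 0.32 with AIA); genotype effects
#' default to zero and are injected additively per effect allele (OXTR G,
#' RS3 L, OPRM1 G).
#'
#' @param n_participants cohort size.
#' @param oxtr_g_freq,oprm1_g_freq G allele frequencies.
#' @param rs3_s_freq frequency of the short RS3 allele.
#' @param p334_given_l probability that a long RS3 allele is the 334 bp
#'   allele.
#' @param alpha_mean,alpha_sd,alpha_bounds truth distribution of alpha.
#' @param beta_mean,beta_sd,beta_bounds truth distribution of beta.
#' @param lambda_meanlog,lambda_sdlog log-normal truth distribution of
#'   lambda (kJPY^-1).
#' @param lambda_fixed if non-NULL, all participants share this lambda.
#' @param effects_alpha,effects_beta named vectors `c(oxtr=, avpr1a=,
#'   oprm1=)` of additive effects per effect allele on alpha / beta.
#' @param age_mean,age_sd,age_bounds age distribution (years).
#' @param age_slope_alpha,age_slope_beta change in alpha / beta per year of
#'   age (applied to age centred at `age_mean`).
#' @param beliefs a [belief_config()] shared with the fitting stage.
#' @param seed master seed; stage-level child seeds derive from it.
#' @return An object of class `"ia_sim_config"`.
#' @export
simulation_config <- function(n_participants = 420,
                              oxtr_g_freq = 0.36,
                              rs3_s_freq = 0.52,
                              p334_given_l = 0.42,
                              oprm1_g_freq = 0.48,
                              alpha_mean = 0.6, alpha_sd = 0.4,
                              alpha_bounds = c(-0.5, 3),
                              beta_mean = 0.4, beta_sd = 0.3,
                              beta_bounds = c(-0.5, 2),
                              lambda_meanlog = log(5), lambda_sdlog = 0.4,
                              lambda_fixed = NULL,
                              effects_alpha = c(oxtr = 0, avpr1a = 0,
                                                oprm1 = 0),
                              effects_beta = c(oxtr = 0, avpr1a = 0,
                                               oprm1 = 0),
                              age_mean = 41, age_sd = 10.5,
                              age_bounds = c(20, 70),
                              age_slope_alpha = 0.13 * 0.4 / 10.5,
                              age_slope_beta = 0.32 * 0.3 / 10.5,
                              beliefs = belief_config(),
                              seed = 1) {
  if (any(c(oxtr_g_freq, rs3_s_freq, p334_given_l, oprm1_g_freq) < 0) ||
      any(c(oxtr_g_freq, rs3_s_freq, p334_given_l, oprm1_g_freq) > 1))
    stop("allele frequencies must lie in [0, 1]")
  if (n_participants < 1) stop("n_participants must be >= 1")
  if (alpha_sd < 0 || beta_sd < 0 || age_sd < 0)
    stop("scales must be non-negative")
  structure(as.list(environment()), class = "ia_sim_config")
}

# inverse-CDF truncated-normal sampler; sd = 0 collapses to the clipped mean
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(pmin(pmax(rep_len(mean, n), lower), upper))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

# variance of Normal(mean, sd) truncated to [a, b]
truncnorm_var <- function(sd, mean = 0, a = -Inf, b = Inf) {
  al <- (a - mean) / sd; be <- (b - mean) / sd
  z <- stats::pnorm(be) - stats::pnorm(al)
  fa <- if (is.finite(al)) al * stats::dnorm(al) else 0
  fb <- if (is.finite(be)) be * stats::dnorm(be) else 0
  da <- if (is.finite(al)) stats::dnorm(al) else 0
  db <- if (is.finite(be)) stats::dnorm(be) else 0
  sd^2 * (1 + (fa - fb) / z - ((da - db) / z)^2)
}

draw_biallelic <- function(n, freq_effect, labels = c("AA", "AG", "GG")) {
  count <- stats::rbinom(n, 2, freq_effect)
  labels[count + 1L]
}

#' Sample a genotype table under Hardy-Weinberg equilibrium
#'
#' Two alleles are drawn independently per gene (HWE holds by construction).
#' RS3 allele lengths are integers drawn around the 330 bp threshold (short:
#' even lengths 310-328, long: 330-350) so the short/long classification
#' recovers the intended allele class; the 334 bp allele is emitted at rate
#' `p334_given_l` among long alleles.
#'
#' @param config a [simulation_config()].
#' @param seed seed (default: derived from the config master seed).
#' @return Genotype data frame (participant_id, oxtr, avpr1a_allele1_bp,
#'   avpr1a_allele2_bp, oprm1, age, sex).
#' @export
sample_genotypes <- function(config, seed = config$seed) {
  set.seed(seed)
  n <- config$n_participants
  draw_rs3_allele <- function(n) {
    is_l <- stats::runif(n) >= config$rs3_s_freq
    len <- integer(n)
    len[!is_l] <- sample(seq(310L, 328L, by = 2L), sum(!is_l),
                         replace = TRUE)
    nl <- sum(is_l)
    if (nl > 0) {
      is334 <- stats::runif(nl) < config$p334_given_l
      other_l <- setdiff(seq(330L, 350L, by = 2L), 334L)
      ll <- integer(nl)
      ll[is334] <- 334L
      ll[!is334] <- sample(other_l, sum(!is334), replace = TRUE)
      len[is_l] <- ll
    }
    len
  }
  data.frame(
    participant_id = sprintf("P%04d", seq_len(n)),
    oxtr = draw_biallelic(n, config$oxtr_g_freq),
    avpr1a_allele1_bp = draw_rs3_allele(n),
    avpr1a_allele2_bp = draw_rs3_allele(n),
    oprm1 = draw_biallelic(n, config$oprm1_g_freq),
    age = round(rtruncnorm(n, config$age_mean, config$age_sd,
                           config$age_bounds[1], config$age_bounds[2]), 1),
    sex = sample(c("female", "male"), n, replace = TRUE),
    stringsAsFactors = FALSE)
}

effect_allele_counts <- function(genotypes) {
  cbind(oxtr = vapply(strsplit(genotypes$oxtr, ""), function(a)
          sum(a == "G"), numeric(1)),
        avpr1a = (classify_rs3_allele(genotypes$avpr1a_allele1_bp) == "L") +
          (classify_rs3_allele(genotypes$avpr1a_allele2_bp) == "L"),
        oprm1 = vapply(strsplit(genotypes$oprm1, ""), function(a)
          sum(a == "G"), numeric(1)))
}

#' Sample true preference parameters given genotypes
#'
#' `beta = beta_mean + sum(effect * effect-allele count) + age_slope *
#' (age - age_mean) + noise`, truncated to the configured bounds; alpha
#' analogous; lambda from its log-normal truth distribution (or fixed).
#'
#' @param genotypes table from [sample_genotypes()].
#' @param config a [simulation_config()].
#' @param seed seed.
#' @return Truth data frame (participant_id, true_alpha, true_beta,
#'   true_lambda).
#' @export
sample_preferences <- function(genotypes, config, seed = config$seed + 1) {
  set.seed(seed)
  n <- nrow(genotypes)
  counts <- effect_allele_counts(genotypes)
  age_c <- genotypes$age - config$age_mean
  ea <- config$effects_alpha[colnames(counts)]
  eb <- config$effects_beta[colnames(counts)]
  if (anyNA(ea) || anyNA(eb))
    stop("effects_alpha / effects_beta must be named c(oxtr=, avpr1a=, oprm1=)")
  mu_a <- config$alpha_mean + drop(counts %*% ea) +
    config$age_slope_alpha * age_c
  mu_b <- config$beta_mean + drop(counts %*% eb) +
    config$age_slope_beta * age_c
  lam <- if (!is.null(config$lambda_fixed)) {
    rep_len(config$lambda_fixed, n)
  } else {
    stats::rlnorm(n, config$lambda_meanlog, config$lambda_sdlog)
  }
  data.frame(
    participant_id = genotypes$participant_id,
    true_alpha = rtruncnorm(n, mu_a, config$alpha_sd,
                            config$alpha_bounds[1], config$alpha_bounds[2]),
    true_beta = rtruncnorm(n, mu_b, config$beta_sd,
                           config$beta_bounds[1], config$beta_bounds[2]),
    true_lambda = lam, stringsAsFactors = FALSE)
}

#' RS3 effect size for a target partial eta-squared
#'
#' Converts a target partial eta-squared of the RS3 factor on *estimated*
#' AIA (the scale on which association studies report effect sizes) into the
#' additive per-L-allele effect on true beta to inject. Posterior-mean
#' estimates are a noisy, shrunken image of the truth, so the injected
#' true-scale effect must be larger than a naive calculation: with
#' attenuation slope `s` (regression of estimate on truth) and estimation
#' noise `est_sd`, the observed genotype variance is `(s * delta)^2 * 2pq`
#' and the observed residual variance `s^2 * v_noise + est_sd^2` (age-driven
#' variance is excluded because age is a model covariate). Defaults for `s`
#' and `est_sd` were measured by a calibration run of the estimation stage
#' at the default study design (see the methods vignette).
#'
#' @param target target partial eta-squared on the estimate scale (e.g.
#'   0.023).
#' @param config a [simulation_config()].
#' @param est_sd measurement noise sd of posterior-mean beta (default 0.20).
#' @param attenuation regression slope of estimated on true beta (default
#'   0.75).
#' @return Per-L-allele additive effect on beta (positive).
#' @export
rs3_effect_for_partial_eta2 <- function(target, config = simulation_config(),
                                        est_sd = 0.20, attenuation = 0.75) {
  stopifnot(target > 0, target < 1)
  p <- config$rs3_s_freq
  q <- 1 - p
  v_noise <- truncnorm_var(config$beta_sd, 0,
                           config$beta_bounds[1] - config$beta_mean,
                           config$beta_bounds[2] - config$beta_mean)
  v_obs <- attenuation^2 * v_noise + est_sd^2
  sqrt(target / (1 - target) * v_obs / (attenuation^2 * 2 * p * q))
}

#' Simulate game choices from true preferences
#'
#' Draws every decision of the schedule independently from the softmax
#' choice probabilities at each participant's true parameters, vectorized
#' across participants context by context.
#'
#' @param truth table from [sample_preferences()] (participant_id,
#'   true_alpha, true_beta, true_lambda).
#' @param contexts decision contexts (default [game_schedule()]; must use
#'   the beliefs the fitting stage will use).
#' @param seed seed.
#' @param scale payoff rescaling divisor.
#' @return Choice data frame (participant_id, game, context_param,
#'   chosen_label), participant-major in schedule order.
#' @export
simulate_choices <- function(truth, contexts = game_schedule(), seed = NULL,
                             scale = payoff_scale) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(truth)
  per_ctx <- lapply(contexts, function(ctx) {
    opt <- ctx$options
    x <- opt$weight * opt$x / scale
    d <- opt$weight * pmax((opt$y - opt$x) / 2, 0) / scale
    a <- opt$weight * pmax((opt$x - opt$y) / 2, 0) / scale
    u <- x - tcrossprod(d, truth$true_alpha) - tcrossprod(a, truth$true_beta)
    v <- u * rep(truth$true_lambda, each = nrow(opt))
    v <- v - rep(apply(v, 2, max), each = nrow(opt))
    p <- exp(v)
    p <- p / rep(colSums(p), each = nrow(opt))
    cum <- apply(p, 2, cumsum)
    pick <- colSums(cum < rep(stats::runif(n), each = nrow(opt))) + 1L
    data.frame(participant_id = truth$participant_id, game = ctx$game,
               context_param = ctx$context_param,
               chosen_label = opt$label[pick], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per_ctx)
  out <- out[order(match(out$participant_id, truth$participant_id)), ]
  rownames(out) <- NULL
  out
}

#' Generate a complete synthetic study
#'
#' Draws genotypes, true preferences and game choices with child seeds
#' derived from the master seed, optionally writing the three CSV files
#' (behaviour, genotypes, truth) plus a JSON log of the configuration.
#'
#' @param config a [simulation_config()].
#' @param dir if non-NULL, directory to write behaviour.csv, genotypes.csv,
#'   truth.csv and study_config.json into.
#' @return List with elements `behaviour`, `genotypes`, `truth`, `config`.
#' @export
generate_study <- function(config = simulation_config(), dir = NULL) {
  set.seed(config$seed)
  child <- sample.int(.Machine$integer.max - 1L, 3)
  genotypes <- sample_genotypes(config, seed = child[1])
  truth <- sample_preferences(genotypes, config, seed = child[2])
  behaviour <- simulate_choices(truth, game_schedule(config$beliefs),
                                seed = child[3])
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    utils::write.csv(behaviour, file.path(dir, "behaviour.csv"),
                     row.names = FALSE)
    utils::write.csv(genotypes, file.path(dir, "genotypes.csv"),
                     row.names = FALSE)
    utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
    cfg <- config
    cfg$beliefs <- unclass(cfg$beliefs)
    jsonlite::write_json(unclass(cfg), file.path(dir, "study_config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  list(behaviour = behaviour, genotypes = genotypes, truth = truth,
       config = config)
}
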