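# Shared fixtures: small deterministic tables and light sampler settings.

light_mcmc <- function(seed = 1, chains = 2, iters = 600) {
  mcmc_config(n_chains = chains, n_warmup = iters, n_samples = iters,
              seed = seed)
}

# Deterministic genotype table realizing given per-gene genotype counts and
# a given number of 334 bp carriers (placed among SL then LL individuals).
genotypes_from_counts <- function(oxtr = c(171, 196, 53),
                                  rs3 = c(117, 203, 100),
                                  oprm1 = c(114, 201, 105),
                                  n334 = 154) {
  n <- sum(oxtr)
  stopifnot(sum(rs3) == n, sum(oprm1) == n)
  a1 <- c(rep(320L, rs3[1]), rep(320L, rs3[2]), rep(340L, rs3[3]))
  a2 <- c(rep(322L, rs3[1]), rep(340L, rs3[2]), rep(342L, rs3[3]))
  carrier_slots <- which(a1 >= 330 | a2 >= 330)
  stopifnot(n334 <= length(carrier_slots))
  a2[carrier_slots[seq_len(n334)]] <- 334L
  data.frame(
    participant_id = sprintf("G%04d", seq_len(n)),
    oxtr = rep(c("AA", "AG", "GG"), oxtr),
    avpr1a_allele1_bp = a1,
    avpr1a_allele2_bp = a2,
    oprm1 = rep(c("AA", "AG", "GG"), oprm1),
    age = rep(seq(25, 60, length.out = 10), length.out = n),
    sex = rep(c("female", "male"), length.out = n),
    stringsAsFactors = FALSE)
}

# A small association-stage dataset with factors/covariate, no model fitted.
random_assoc_data <- function(n, seed, effect_avpr1a = 0) {
  set.seed(seed)
  d <- data.frame(
    oxtr = factor(sample(c("AA", "AG", "GG"), n, TRUE),
                  levels = c("AA", "AG", "GG")),
    avpr1a = factor(sample(c("SS", "SL", "LL"), n, TRUE),
                    levels = c("SS", "SL", "LL")),
    oprm1 = factor(sample(c("AA", "AG", "GG"), n, TRUE),
                   levels = c("AA", "AG", "GG")),
    age = round(runif(n, 20, 65), 1))
  d$y <- 0.4 + 0.01 * (d$age - 41) +
    effect_avpr1a * (as.integer(d$avpr1a) - 1) + rnorm(n, 0, 0.3)
  d
}
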