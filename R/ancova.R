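# Gene-preference association statistics: ANCOVA with Type-III marginal
# tests, partial eta-squared, and Bonferroni-corrected pairwise contrasts of
# covariate-adjusted means.

#' Per-comparison Bonferroni threshold
#'
#' @param k number of pairwise comparisons (3 for a three-genotype factor).
#' @param alpha family-wise error rate.
#' @return `alpha / k` (0.0167 for three genotypes, conventionally reported
#'   as 0.017).
#' @export
bonferroni_threshold <- function(k, alpha = 0.05) {
  stopifnot(k >= 1)
  alpha / k
}

#' ANCOVA with Type-III marginal tests and partial eta-squared
#'
#' Fits a linear model (sum-to-zero contrasts on all factor predictors) and
#' tests each term marginally, i.e. against the model containing all other
#' terms (Type-III sums of squares, the SAS convention). Partial eta-squared
#' is `SS_term / (SS_term + SS_error)`. With three 3-level genotype factors
#' and an age covariate at n participants the error df is n - 8.
#'
#' @param formula model formula, e.g.
#'   `beta_mean ~ oxtr + avpr1a + oprm1 + age`.
#' @param data data frame holding the dependent variable, genotype factors
#'   and covariates.
#' @return An object of class `"ia_ancova"`: `table` (term, F, df1, df2, p,
#'   partial_eta2), the fitted `model` and the raw `anova` table.
#' @export
ia_ancova <- function(formula, data) {
  mf <- stats::model.frame(formula, data = data)
  fac <- names(mf)[-1][vapply(mf[-1], is.factor, logical(1))]
  for (f in fac) {
    if (nlevels(droplevels(mf[[f]])) < 2)
      stop("factor '", f, "' has fewer than 2 observed levels")
  }
  contr <- stats::setNames(rep(list("contr.sum"), length(fac)), fac)
  mod <- stats::lm(formula, data = data,
                   contrasts = if (length(fac)) contr else NULL)
  mm <- stats::model.matrix(mod)
  if (mod$rank < ncol(mm)) {
    aliased <- colnames(mm)[is.na(stats::coef(mod))]
    stop("rank-deficient design; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
  if (stats::df.residual(mod) <= 0)
    stop("no residual degrees of freedom (n <= model df)")
  if (sum(stats::residuals(mod)^2) < 1e-10 &&
      stats::var(stats::model.response(mf)) < 1e-20) {
    # constant dependent: every factor contributes nothing; define F = 0
    trm <- attr(stats::terms(mod), "term.labels")
    dfs <- vapply(trm, function(tm) {
      idx <- which(attr(mm, "assign") == match(tm, trm))
      length(idx)
    }, integer(1))
    tab <- data.frame(term = trm, F = 0, df1 = dfs,
                      df2 = stats::df.residual(mod), p = 1,
                      partial_eta2 = 0, stringsAsFactors = FALSE)
    return(structure(list(table = tab, model = mod, anova = NULL, mse = 0,
                          formula = formula, n = nrow(mf)),
                     class = "ia_ancova"))
  }
  a <- car::Anova(mod, type = 3)
  terms_keep <- setdiff(rownames(a), c("(Intercept)", "Residuals"))
  ss_err <- a["Residuals", "Sum Sq"]
  df_err <- a["Residuals", "Df"]
  mse <- ss_err / df_err
  tab <- do.call(rbind, lapply(terms_keep, function(tm) {
    ss <- a[tm, "Sum Sq"]
    df1 <- a[tm, "Df"]
    if (ss < 1e-12 && mse < 1e-12) {
      # degenerate outcome (e.g. constant dependent): define F = 0
      f <- 0; p <- 1; peta <- 0
    } else {
      f <- (ss / df1) / mse
      p <- stats::pf(f, df1, df_err, lower.tail = FALSE)
      peta <- ss / (ss + ss_err)
    }
    data.frame(term = tm, F = f, df1 = df1, df2 = df_err, p = p,
               partial_eta2 = peta, stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  structure(list(table = tab, model = mod, anova = a, mse = mse,
                 formula = formula, n = nrow(mf)),
            class = "ia_ancova")
}

#' @export
print.ia_ancova <- function(x, ...) {
  cat("ANCOVA (Type-III marginal tests), n =", x$n, "\n")
  cat("  ", deparse(x$formula), "\n")
  tab <- x$table
  tab$F <- round(tab$F, 2)
  tab$p <- signif(tab$p, 3)
  tab$partial_eta2 <- round(tab$partial_eta2, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Bonferroni-corrected pairwise contrasts of adjusted means
#'
#' Pairwise comparisons of the factor's covariate-adjusted means (covariates
#' held at their grand mean), tested with the ANCOVA error term (df = error
#' df). The per-comparison significance threshold is `alpha / #contrasts`
#' (0.017 for three genotypes); Cohen's d is the adjusted-mean difference
#' divided by the root mean squared error of the model.
#'
#' @param fit an [ia_ancova()] fit.
#' @param factor name of a factor in the model (e.g. `"avpr1a"`).
#' @param alpha family-wise error rate (default 0.05).
#' @return Data frame of class `"ia_contrasts"`: contrast, estimate, t, df,
#'   p (uncorrected), threshold, significant, d.
#' @export
pairwise_bonferroni <- function(fit, factor, alpha = 0.05) {
  stopifnot(inherits(fit, "ia_ancova"))
  emm <- suppressWarnings(suppressMessages(
    emmeans::emmeans(fit$model, specs = factor)))
  prs <- as.data.frame(suppressWarnings(suppressMessages(
    emmeans::contrast(emm, method = "pairwise", adjust = "none"))))
  thr <- bonferroni_threshold(nrow(prs), alpha)
  est <- prs$estimate
  tval <- prs$t.ratio
  pval <- prs$p.value
  dd <- if (fit$mse > 0) est / sqrt(fit$mse) else rep(0, length(est))
  zero <- abs(est) < 1e-12
  tval[zero] <- 0; dd[zero] <- 0; pval[zero] <- 1
  out <- data.frame(contrast = as.character(prs$contrast), estimate = est,
                    t = tval, df = prs$df, p = pval, threshold = thr,
                    significant = pval < thr, d = dd,
                    stringsAsFactors = FALSE)
  class(out) <- c("ia_contrasts", "data.frame")
  out
}

#' @export
print.ia_contrasts <- function(x, ...) {
  cat(sprintf("Pairwise contrasts (Bonferroni threshold %.3f)\n",
              x$threshold[1]))
  print.data.frame(x, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Gene-preference association analysis
#'
#' Runs, for each dependent preference estimate (DIA then AIA), the ANCOVA
#' with the three genotype factors entered together plus covariates, and
#' pairwise Bonferroni contrasts for every 3-level genotype factor. With
#' `use_334 = TRUE` the AVPR1A factor is replaced by 334 bp carrier status
#' (2 levels, no pairwise table). `sex_interaction = TRUE` adds sex and
#' sex-by-gene interaction terms.
#'
#' @param estimates cohort estimates table (from [estimate_cohort()] or
#'   [read_estimates_csv()]), with alpha_mean and beta_mean columns.
#' @param genotypes raw genotype table; coded internally with
#'   [code_genotypes()].
#' @param deps named character vector mapping report labels to estimate
#'   columns (default DIA = alpha_mean, AIA = beta_mean).
#' @param covariates covariate column names (default "age").
#' @param use_334 use 334 bp carrier status instead of the S/L genotype.
#' @param sex_interaction add sex main effect and sex-by-gene interactions.
#' @return An object of class `"ia_association"`: `anova` (one row per
#'   dependent x term) and `contrasts` (per dependent x factor x pair), plus
#'   the per-dependent [ia_ancova()] fits.
#' @export
associate_preferences <- function(estimates, genotypes,
                                  deps = c(DIA = "alpha_mean",
                                           AIA = "beta_mean"),
                                  covariates = "age", use_334 = FALSE,
                                  sex_interaction = FALSE) {
  g <- code_genotypes(genotypes)
  merged <- merge(as.data.frame(estimates), g, by = "participant_id")
  if (nrow(merged) == 0)
    stop("no participants shared between estimates and genotype tables")
  gene_terms <- c("oxtr", if (use_334) "carrier334" else "avpr1a", "oprm1")
  rhs <- c(gene_terms, covariates)
  if (sex_interaction)
    rhs <- c(rhs, "sex", paste0("sex:", gene_terms))
  fits <- list()
  anova_rows <- list()
  contrast_rows <- list()
  for (lab in names(deps)) {
    fml <- stats::reformulate(rhs, response = deps[[lab]])
    fit <- ia_ancova(fml, merged)
    fits[[lab]] <- fit
    anova_rows[[lab]] <- cbind(dependent = lab, fit$table)
    for (fac in gene_terms) {
      if (nlevels(merged[[fac]]) == 3) {
        ct <- pairwise_bonferroni(fit, fac)
        contrast_rows[[paste(lab, fac)]] <-
          cbind(dependent = lab, factor = fac, as.data.frame(ct))
      }
    }
  }
  structure(list(anova = do.call(rbind, anova_rows),
                 contrasts = do.call(rbind, contrast_rows),
                 fits = fits, n = nrow(merged)),
            class = "ia_association")
}

#' @export
print.ia_association <- function(x, ...) {
  cat(sprintf("Gene-preference association (n = %d)\n", x$n))
  tab <- x$anova
  tab$F <- round(tab$F, 2)
  tab$p <- signif(tab$p, 3)
  tab$partial_eta2 <- round(tab$partial_eta2, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}
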