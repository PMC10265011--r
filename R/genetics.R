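# Genotype coding and genotype-distribution tests.
#
# AVPR1A RS3 is a promoter microsatellite; allele lengths (bp) are
# dichotomized at the sample-median threshold of 330 bp: < 330 is "short"
# (S), >= 330 is "long" (L). The 334 bp allele is additionally tracked as a
# specific risk allele (carrier = at least one 334 bp allele).

#' Classify an RS3 allele length as short or long
#'
#' @param length_bp allele length(s) in base pairs (positive integers).
#' @param threshold_bp short/long boundary; lengths strictly below are "S",
#'   lengths at or above are "L" (default 330, the sample median).
#' @return Character vector of "S"/"L".
#' @export
classify_rs3_allele <- function(length_bp, threshold_bp = 330) {
  if (any(length_bp <= 0)) stop("allele lengths must be positive")
  ifelse(length_bp < threshold_bp, "S", "L")
}

#' RS3 genotype from two allele lengths
#'
#' Order-insensitive: (320, 340) and (340, 320) are both "SL".
#'
#' @param a1_bp,a2_bp the two allele lengths in bp.
#' @param threshold_bp see [classify_rs3_allele()].
#' @return Character vector of "SS"/"SL"/"LL".
#' @export
rs3_genotype <- function(a1_bp, a2_bp, threshold_bp = 330) {
  c1 <- classify_rs3_allele(a1_bp, threshold_bp)
  c2 <- classify_rs3_allele(a2_bp, threshold_bp)
  n_s <- (c1 == "S") + (c2 == "S")
  c("LL", "SL", "SS")[n_s + 1L]
}

#' 334 bp allele carrier status
#'
#' @param a1_bp,a2_bp the two RS3 allele lengths in bp.
#' @return Logical: TRUE iff either allele is exactly 334 bp.
#' @export
carrier_334 <- function(a1_bp, a2_bp) {
  if (any(c(a1_bp, a2_bp) <= 0)) stop("allele lengths must be positive")
  a1_bp == 334 | a2_bp == 334
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' Pearson goodness-of-fit test with 1 df, no continuity correction: the
#' allele frequency is estimated from the genotype counts and expected
#' counts are (p^2 n, 2pq n, q^2 n). The result is invariant to which
#' homozygote is listed first. A monomorphic sample returns chi-square 0
#' with a warning.
#'
#' @param counts integer vector of length 3: (hom1, het, hom2) counts.
#' @return List with `chi2`, `df` (= 1), `p`, and the `expected` counts.
#' @export
hwe_chisq <- function(counts) {
  if (length(counts) != 3 || any(counts < 0) || sum(counts) == 0)
    stop("counts must be three non-negative genotype counts with total > 0")
  n <- sum(counts)
  p <- (2 * counts[1] + counts[2]) / (2 * n)
  q <- 1 - p
  if (p == 0 || p == 1) {
    warning("monomorphic sample: HWE chi-square defined as 0")
    return(list(chi2 = 0, df = 1L, p = 1, expected = counts))
  }
  expected <- n * c(p^2, 2 * p * q, q^2)
  chi2 <- sum((counts - expected)^2 / expected)
  list(chi2 = chi2, df = 1L, p = stats::pchisq(chi2, 1, lower.tail = FALSE),
       expected = expected)
}

#' Genotype-independence chi-square test for a 3 x 3 table
#'
#' Standard Pearson independence test (4 df), no continuity correction.
#'
#' @param table 3 x 3 matrix of genotype cross-counts.
#' @return List with `chi2`, `df` (= 4), `p`.
#' @export
crosstab_chisq <- function(table) {
  table <- as.matrix(table)
  if (sum(table) == 0) stop("table total must be > 0")
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value))
}

#' Pearson correlation with t-based p value
#'
#' @param u,v numeric vectors of equal length n >= 3.
#' @return List with `r`, `df` (= n - 2), `t`, `p`.
#' @export
pearson_corr <- function(u, v) {
  if (length(u) != length(v) || length(u) < 3)
    stop("pearson_corr needs two vectors of equal length >= 3")
  ct <- stats::cor.test(u, v, method = "pearson")
  list(r = unname(ct$estimate), df = unname(ct$parameter),
       t = unname(ct$statistic), p = unname(ct$p.value))
}

#' Add genotype codings to a raw genotype table
#'
#' Adds `avpr1a` (SS/SL/LL from the two RS3 allele lengths) and
#' `carrier334` columns and turns the three genotype columns into factors
#' with fixed level order.
#'
#' @param genotypes data frame with columns participant_id, oxtr,
#'   avpr1a_allele1_bp, avpr1a_allele2_bp, oprm1, age, sex.
#' @param threshold_bp RS3 short/long boundary.
#' @return The coded data frame.
#' @export
code_genotypes <- function(genotypes, threshold_bp = 330) {
  validate_genotypes(genotypes)
  genotypes$avpr1a <- factor(rs3_genotype(genotypes$avpr1a_allele1_bp,
                                          genotypes$avpr1a_allele2_bp,
                                          threshold_bp),
                             levels = c("SS", "SL", "LL"))
  genotypes$carrier334 <- factor(ifelse(
    carrier_334(genotypes$avpr1a_allele1_bp, genotypes$avpr1a_allele2_bp),
    "carrier", "non_carrier"), levels = c("non_carrier", "carrier"))
  genotypes$oxtr <- factor(genotypes$oxtr, levels = c("AA", "AG", "GG"))
  genotypes$oprm1 <- factor(genotypes$oprm1, levels = c("AA", "AG", "GG"))
  genotypes$sex <- factor(genotypes$sex, levels = c("female", "male"))
  genotypes
}

validate_genotypes <- function(genotypes) {
  need <- c("participant_id", "oxtr", "avpr1a_allele1_bp",
            "avpr1a_allele2_bp", "oprm1", "age", "sex")
  miss <- setdiff(need, names(genotypes))
  if (length(miss))
    stop("genotype table is missing column(s): ",
         paste(miss, collapse = ", "))
  bad <- which(!(genotypes$oxtr %in% c("AA", "AG", "GG")) |
               !(genotypes$oprm1 %in% c("AA", "AG", "GG")) |
               genotypes$avpr1a_allele1_bp <= 0 |
               genotypes$avpr1a_allele2_bp <= 0 |
               genotypes$age <= 0 |
               !(genotypes$sex %in% c("female", "male")))
  if (length(bad))
    stop("invalid genotype rows: ", paste(bad, collapse = ", "))
  invisible(genotypes)
}

#' Genotype-distribution report
#'
#' Reproduces, from any genotype table, the descriptive genotype summary of
#' a candidate-gene study: per-gene genotype counts and percentages (1
#' decimal), the HWE chi-square, and the 334 bp carrier split.
#'
#' @param genotypes raw or [code_genotypes()]-coded genotype table.
#' @return An object of class `"ia_genotype_report"`: list with `table`
#'   (gene, genotype, n, pct), `hwe` (gene, chi2, df, p) and `carrier334`
#'   (n, pct per status).
#' @export
genotype_report <- function(genotypes) {
  g <- code_genotypes(genotypes)
  genes <- list(OXTR = table(g$oxtr), AVPR1A = table(g$avpr1a),
                OPRM1 = table(g$oprm1))
  tab <- do.call(rbind, lapply(names(genes), function(gene) {
    tt <- genes[[gene]]
    data.frame(gene = gene, genotype = names(tt), n = as.integer(tt),
               pct = round(100 * as.integer(tt) / sum(tt), 1),
               stringsAsFactors = FALSE)
  }))
  hwe <- do.call(rbind, lapply(names(genes), function(gene) {
    h <- hwe_chisq(as.integer(genes[[gene]]))
    data.frame(gene = gene, chi2 = h$chi2, df = h$df, p = h$p,
               stringsAsFactors = FALSE)
  }))
  carr <- table(g$carrier334)
  carrier <- data.frame(status = names(carr), n = as.integer(carr),
                        pct = round(100 * as.integer(carr) / sum(carr), 1),
                        stringsAsFactors = FALSE)
  structure(list(table = tab, hwe = hwe, carrier334 = carrier,
                 n = nrow(g)),
            class = "ia_genotype_report")
}

#' @export
print.ia_genotype_report <- function(x, ...) {
  cat(sprintf("Genotype distribution (n = %d)\n", x$n))
  for (gene in unique(x$table$gene)) {
    rows <- x$table[x$table$gene == gene, ]
    h <- x$hwe[x$hwe$gene == gene, ]
    cat(sprintf("  %-7s %s | HWE chi2(1) = %.3f, p = %.3f\n", gene,
                paste(sprintf("%s %.1f%% (n = %d)", rows$genotype, rows$pct,
                              rows$n), collapse = ", "),
                h$chi2, h$p))
  }
  cc <- x$carrier334
  cat(sprintf("  334 bp: %s\n",
              paste(sprintf("%s %.1f%% (n = %d)", cc$status, cc$pct, cc$n),
                    collapse = ", ")))
  invisible(x)
}
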