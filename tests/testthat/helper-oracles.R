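# Independent normal-equations oracle for the ANCOVA stage: sum-to-zero
# dummy coding built by hand, least squares via solve(crossprod()), Type-III
# F by full-vs-reduced SSE comparison, contrasts of adjusted means from the
# coefficient covariance. Shares no code with ia_ancova()/emmeans.

oracle_design <- function(data, factors, covariates) {
  X <- matrix(1, nrow(data), 1)
  cols <- list()
  for (f in factors) {
    lv <- levels(data[[f]])
    k <- length(lv)
    M <- matrix(0, nrow(data), k - 1)
    for (j in seq_len(k - 1)) {
      M[data[[f]] == lv[j], j] <- 1
      M[data[[f]] == lv[k], j] <- -1
    }
    cols[[f]] <- ncol(X) + seq_len(k - 1)
    X <- cbind(X, M)
  }
  for (cv in covariates) {
    cols[[cv]] <- ncol(X) + 1L
    X <- cbind(X, data[[cv]])
  }
  list(X = X, cols = cols)
}

oracle_typeIII <- function(data, dep, factors, covariates) {
  dz <- oracle_design(data, factors, covariates)
  X <- dz$X
  y <- data[[dep]]
  bhat <- solve(crossprod(X), crossprod(X, y))
  sse_full <- sum((y - X %*% bhat)^2)
  dfe <- nrow(X) - ncol(X)
  rows <- lapply(c(factors, covariates), function(tm) {
    keep <- setdiff(seq_len(ncol(X)), dz$cols[[tm]])
    Xr <- X[, keep, drop = FALSE]
    br <- solve(crossprod(Xr), crossprod(Xr, y))
    ss <- sum((y - Xr %*% br)^2) - sse_full
    q <- length(dz$cols[[tm]])
    data.frame(term = tm, F = (ss / q) / (sse_full / dfe), df1 = q,
               df2 = dfe, peta2 = ss / (ss + sse_full),
               stringsAsFactors = FALSE)
  })
  list(table = do.call(rbind, rows), sse = sse_full, dfe = dfe,
       bhat = drop(bhat), XtX_inv = solve(crossprod(X)), cols = dz$cols)
}

# t statistics for pairwise differences of covariate-adjusted means of one
# 3-level factor (other factors averaged out, covariates at grand mean);
# with sum-to-zero coding the difference reduces to a contrast of the
# factor's own coefficients.
oracle_pairwise_t <- function(orc, data, factor) {
  idx <- orc$cols[[factor]]
  lv <- levels(data[[factor]])
  eff <- function(l) {          # coefficient row vector for level l's effect
    v <- numeric(length(orc$bhat))
    j <- match(l, lv)
    if (j < length(lv)) v[idx[j]] <- 1 else v[idx] <- -1
    v
  }
  mse <- orc$sse / orc$dfe
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  do.call(rbind, lapply(pairs, function(pr) {
    L <- eff(pr[1]) - eff(pr[2])
    est <- sum(L * orc$bhat)
    se <- sqrt(drop(t(L) %*% orc$XtX_inv %*% L) * mse)
    data.frame(contrast = paste(pr[1], "-", pr[2]), estimate = est,
               t = est / se, stringsAsFactors = FALSE)
  }))
}
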