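#' Orthogonal Cockerham coding of a genotype vector
#'
#' Each biallelic genotype `g` (0/1/2 counted-allele copies) is decomposed
#' into an additive score `x = g - 1` (-1, 0, +1) and a dominance score
#' `z` (+0.5 for heterozygotes, -0.5 for homozygotes). Under HWE with allele
#' frequency 0.5 both scores have mean zero and are uncorrelated, which makes
#' the four interaction products x1x2, x1z2, z1x2, z1z2 an orthogonal
#' partition of the two-locus interaction. Missing calls propagate.
#'
#' @param g genotype vector with values in `{0, 1, 2, NA}`.
#' @return List with numeric vectors `x` and `z`.
#' @export
cockerham_code <- function(g) {
  bad <- !is.na(g) & !(g %in% 0:2)
  if (any(bad)) stop("genotype values outside {0, 1, 2}: ",
                     paste(unique(g[bad]), collapse = ", "))
  list(x = as.numeric(g) - 1,
       z = ifelse(is.na(g), NA_real_, ifelse(g == 1, 0.5, -0.5)))
}

# classed condition so scan loops can log-and-skip degenerate pairs
stop_skip <- function(...) {
  stop(structure(class = c("epipair_skip", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# OLS by QR with coefficient covariance; errors (classed) on rank deficiency
ols_fit <- function(X, y) {
  q <- qr(X)
  if (q$rank < ncol(X)) {
    bad <- colnames(X)[q$pivot[(q$rank + 1):ncol(X)]]
    stop_skip("rank-deficient design; collinear columns: ",
              paste(bad, collapse = ", "))
  }
  beta <- qr.coef(q, y)
  res <- y - drop(X %*% beta)
  rss <- sum(res^2)
  df <- nrow(X) - ncol(X)
  XtXinv <- chol2inv(qr.R(q))
  piv <- q$pivot
  XtXinv[piv, piv] <- XtXinv
  se <- sqrt(pmax(diag(XtXinv), 0) * rss / df)
  names(se) <- names(beta)
  list(beta = beta, se = se, rss = rss, df = df, resid = res)
}

#' Fit the two-locus Cockerham interaction models for a SNP pair
#'
#' Fits, by ordinary least squares over complete cases, the no-interaction
#' model (1)
#' `y = C b0 + a1 x1 + d1 z1 + a2 x2 + d2 z2 + e`
#' and the full model (2) adding the four interaction products
#' `i_aa x1x2 + i_ad x1z2 + i_da z1x2 + i_dd z1z2`.
#'
#' @param y trait vector.
#' @param C covariate design matrix including an intercept column
#'   (see [covariate_design()]).
#' @param g1,g2 genotype vectors in `{0, 1, 2, NA}`.
#' @return Object of class `interaction_fit`: coefficients and SEs for
#'   a1, d1, a2, d2, i_aa, i_ad, i_da, i_dd; `rss1`, `rss2`, `df2`;
#'   `r2_model1`, `r2_model2`; `F`, `p` of the 4-df interaction test;
#'   `n_complete`; covariate block `beta0`.
#' @export
fit_pair <- function(y, C, g1, g2) {
  C <- as.matrix(C)
  n <- length(y)
  stopifnot(nrow(C) == n, length(g1) == n, length(g2) == n)
  ok <- !is.na(y) & !is.na(g1) & !is.na(g2) & stats::complete.cases(C)
  y <- y[ok]; C <- C[ok, , drop = FALSE]
  g1 <- g1[ok]; g2 <- g2[ok]
  if (length(unique(g1)) < 3L || length(unique(g2)) < 3L)
    stop_skip("a genotype class is absent after complete-case restriction")
  if (is.null(colnames(C))) colnames(C) <- paste0("c", seq_len(ncol(C)))
  s1 <- cockerham_code(g1); s2 <- cockerham_code(g2)
  X1 <- cbind(C, a1 = s1$x, d1 = s1$z, a2 = s2$x, d2 = s2$z)
  X2 <- cbind(X1, i_aa = s1$x * s2$x, i_ad = s1$x * s2$z,
              i_da = s1$z * s2$x, i_dd = s1$z * s2$z)
  if (length(y) < ncol(X2) + 1L)
    stop_skip("too few complete cases (", length(y), ") for ",
              ncol(X2), " parameters")
  f1 <- ols_fit(X1, y)
  f2 <- ols_fit(X2, y)
  tss <- sum((y - mean(y))^2)
  df2 <- f2$df
  Fstat <- ((f1$rss - f2$rss) / 4) / (f2$rss / df2)
  terms <- c("a1", "d1", "a2", "d2", "i_aa", "i_ad", "i_da", "i_dd")
  fit <- list(
    coef = f2$beta[terms], se = f2$se[terms],
    beta0 = f2$beta[colnames(C)],
    rss1 = f1$rss, rss2 = f2$rss, df2 = df2,
    F = Fstat, p = stats::pf(Fstat, 4, df2, lower.tail = FALSE),
    r2_model1 = 1 - f1$rss / tss, r2_model2 = 1 - f2$rss / tss,
    n_complete = length(y))
  class(fit) <- "interaction_fit"
  fit
}

#' @export
print.interaction_fit <- function(x, ...) {
  cat(sprintf("two-locus interaction fit (n = %d)\n", x$n_complete))
  tab <- cbind(estimate = x$coef, se = x$se)
  print(round(tab, 4))
  cat(sprintf("4-df interaction F = %.3f, p = %.3g  (R2: %.4f -> %.4f)\n",
              x$F, x$p, x$r2_model1, x$r2_model2))
  invisible(x)
}

#' 4-df interaction F-test between the nested two-locus models
#'
#' `F = ((rss1 - rss2) / 4) / (rss2 / df2)` with p from `F(4, df2)`. This is
#' the omnibus test for an epistatic interaction of any of the four types.
#'
#' @param fit an [fit_pair()] result.
#' @return List with elements `F` and `p`.
#' @export
interaction_f_test <- function(fit) {
  stopifnot(inherits(fit, "interaction_fit"))
  if (fit$rss2 <= 0) stop("saturated model: rss2 = 0, F undefined")
  if (fit$df2 <= 0) stop("no residual degrees of freedom")
  Fstat <- ((fit$rss1 - fit$rss2) / 4) / (fit$rss2 / fit$df2)
  list(F = Fstat, p = stats::pf(Fstat, 4, fit$df2, lower.tail = FALSE))
}

#' Additive-only 1-df interaction test
#'
#' The PLINK-style `--epistasis` analogue: only additive terms and their
#' product are modelled, and the x1*x2 term is tested with 1 df.
#'
#' @inheritParams fit_pair
#' @return List with `F`, `p`, and the interaction coefficient `i_aa`.
#' @export
additive_only_test <- function(y, C, g1, g2) {
  C <- as.matrix(C)
  ok <- !is.na(y) & !is.na(g1) & !is.na(g2) & stats::complete.cases(C)
  y <- y[ok]; C <- C[ok, , drop = FALSE]; g1 <- g1[ok]; g2 <- g2[ok]
  if (is.null(colnames(C))) colnames(C) <- paste0("c", seq_len(ncol(C)))
  x1 <- as.numeric(g1) - 1; x2 <- as.numeric(g2) - 1
  X1 <- cbind(C, a1 = x1, a2 = x2)
  X2 <- cbind(X1, i_aa = x1 * x2)
  if (length(y) < ncol(X2) + 1L) stop_skip("too few complete cases")
  f1 <- ols_fit(X1, y); f2 <- ols_fit(X2, y)
  Fstat <- (f1$rss - f2$rss) / (f2$rss / f2$df)
  list(F = Fstat, p = stats::pf(Fstat, 1, f2$df, lower.tail = FALSE),
       i_aa = unname(f2$beta["i_aa"]))
}

#' Partition the interaction into its four orthogonal components
#'
#' Per-component t-tests (`t = estimate / SE`, `df2` degrees of freedom,
#' two-sided) for i_aa, i_ad, i_da, i_dd, used to compare the *pattern* of
#' interaction across cohorts.
#'
#' @param fit an [fit_pair()] result.
#' @param alpha per-component significance level (default 0.01).
#' @return data.frame with columns component, estimate, se, t, p, significant.
#' @export
partition_components <- function(fit, alpha = 0.01) {
  stopifnot(inherits(fit, "interaction_fit"))
  comp <- c("i_aa", "i_ad", "i_da", "i_dd")
  est <- fit$coef[comp]; se <- fit$se[comp]
  t <- est / se
  p <- 2 * stats::pt(abs(t), df = fit$df2, lower.tail = FALSE)
  data.frame(component = comp, estimate = unname(est), se = unname(se),
             t = unname(t), p = unname(p), significant = unname(p < alpha),
             stringsAsFactors = FALSE)
}

#' Variance explained by the interaction terms
#'
#' @param fit an [fit_pair()] result.
#' @return `r2_model2 - r2_model1`, the additional fraction of trait variance
#'   explained by the four interaction terms (non-negative by nesting).
#' @export
delta_r2 <- function(fit) {
  stopifnot(inherits(fit, "interaction_fit"))
  max(0, fit$r2_model2 - fit$r2_model1)
}

#' Bonferroni correction
#'
#' @param p raw p-value(s).
#' @param m number of tests.
#' @return `min(1, p * m)`, elementwise.
#' @export
bonferroni <- function(p, m) {
  stopifnot(m >= 1, all(p >= 0 & p <= 1))
  pmin(1, p * m)
}
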