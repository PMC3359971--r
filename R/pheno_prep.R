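#' Average repeated trait measurements
#'
#' Lipid levels (and age and BMI) measured at multiple visits are averaged
#' per individual; missing visits are skipped.
#'
#' @param x numeric vector of per-visit values (with `NA` for missed visits).
#' @return Arithmetic mean of the non-missing values, or `NA` if all are
#'   missing (the individual is then excluded downstream).
#' @export
average_trait <- function(x) {
  if (all(is.na(x))) return(NA_real_)
  mean(x, na.rm = TRUE)
}

#' Log-transform triglyceride levels
#'
#' TG distributions are right-skewed; the natural log is applied before
#' analysis. Any log base is monotone-equivalent for testing.
#'
#' @param tg positive TG value(s).
#' @return `log(tg)`.
#' @export
transform_tg <- function(tg) {
  if (any(!is.na(tg) & tg <= 0))
    stop("TG must be positive for log transformation")
  log(tg)
}

#' Exclude individuals on lipid-lowering medication
#'
#' Individuals *known* to be medicated are removed; a missing flag is treated
#' as not medicated.
#'
#' @param tab data.frame with one row per individual.
#' @param med_flag logical vector (or column name in `tab`) flagging
#'   medication use.
#' @return `tab` restricted to unmedicated individuals.
#' @export
exclude_medicated <- function(tab, med_flag) {
  if (is.character(med_flag) && length(med_flag) == 1L)
    med_flag <- tab[[med_flag]]
  med_flag <- as.logical(med_flag)
  med_flag[is.na(med_flag)] <- FALSE
  tab[!med_flag, , drop = FALSE]
}

#' Build an analysis-ready phenotype table from visit-level records
#'
#' Averages each trait (and age, BMI) over visits per individual, applies the
#' TG log transform, excludes medicated individuals, and assembles the
#' covariate columns sex, age, age^2 (square of the averaged age), BMI, and
#' optionally plate.
#'
#' @param visits data.frame with columns `sample_id`, trait columns named in
#'   `traits`, `sex`, `age`, `bmi`, optionally `plate` and `med` (medication
#'   flag); one row per visit.
#' @param traits character vector of trait column names; any column named
#'   `"TG"` (case-insensitive) is log-transformed after averaging.
#' @return data.frame, one row per retained individual: `sample_id`, averaged
#'   traits, `sex`, `age`, `age2`, `bmi`, and `plate` when present.
#' @export
prepare_phenotypes <- function(visits, traits) {
  stopifnot("sample_id" %in% names(visits), all(traits %in% names(visits)))
  ids <- unique(visits$sample_id)
  one <- function(col, id) average_trait(visits[[col]][visits$sample_id == id])
  out <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  for (tr in traits) out[[tr]] <- vapply(ids, function(i) one(tr, i), 0)
  for (cv in c("age", "bmi"))
    if (cv %in% names(visits))
      out[[cv]] <- vapply(ids, function(i) one(cv, i), 0)
  first_of <- function(col)
    vapply(ids, function(i) visits[[col]][visits$sample_id == i][1L],
           visits[[col]][1L])
  if ("sex" %in% names(visits)) out$sex <- first_of("sex")
  if ("plate" %in% names(visits)) out$plate <- first_of("plate")
  if ("age" %in% names(out)) out$age2 <- out$age^2
  tg_col <- traits[toupper(traits) == "TG"]
  for (tc in tg_col) out[[tc]] <- transform_tg(out[[tc]])
  if ("med" %in% names(visits)) {
    med <- vapply(ids, function(i) {
      f <- visits$med[visits$sample_id == i]
      any(!is.na(f) & as.logical(f))
    }, TRUE)
    out <- out[!med, , drop = FALSE]
  }
  out
}

#' Covariate design matrix
#'
#' Builds the standard covariate block: intercept, sex, age, age^2, BMI,
#' plate indicators (when a plate column is present) and any PC columns.
#'
#' @param pheno data.frame as returned by [prepare_phenotypes()], possibly
#'   with `PC1..PCk` columns appended.
#' @return Numeric design matrix with an intercept column.
#' @export
covariate_design <- function(pheno) {
  cols <- list(intercept = rep(1, nrow(pheno)))
  for (v in c("sex", "age", "age2", "bmi"))
    if (v %in% names(pheno)) cols[[v]] <- as.numeric(pheno[[v]])
  if ("plate" %in% names(pheno)) {
    pl <- factor(pheno$plate)
    if (nlevels(pl) > 1) {
      mm <- stats::model.matrix(~ pl)[, -1, drop = FALSE]
      colnames(mm) <- paste0("plate", levels(pl)[-1])
      for (cn in colnames(mm)) cols[[cn]] <- mm[, cn]
    }
  }
  for (v in grep("^PC[0-9]+$", names(pheno), value = TRUE))
    cols[[v]] <- as.numeric(pheno[[v]])
  do.call(cbind, cols)
}

#' Principal components of a genotype matrix
#'
#' Columns are mean-imputed, centred, and scaled by the binomial standard
#' deviation `sqrt(2 f (1 - f))` implied by the allele frequency `f`; the
#' top-`k` left singular vectors of the standardized matrix are returned
#' (the usual genotype-PCA construction). Monomorphic columns are dropped.
#'
#' @param gm a [geno_matrix()] (hidden columns are excluded).
#' @param k number of components (default 10).
#' @return n x k matrix of PC coordinates (columns `PC1..PCk`), unit-norm
#'   directions scaled by their singular values.
#' @export
compute_pcs <- function(gm, k = 10) {
  gm <- visible_variants(gm)
  x <- gm$calls
  storage.mode(x) <- "double"
  f <- colMeans(x, na.rm = TRUE) / 2
  poly <- !is.na(f) & f > 0 & f < 1
  if (!any(poly)) stop("no polymorphic SNPs; PCA undefined")
  x <- x[, poly, drop = FALSE]; f <- f[poly]
  for (j in seq_len(ncol(x))) {
    xj <- x[, j]
    xj[is.na(xj)] <- 2 * f[j]
    x[, j] <- (xj - 2 * f[j]) / sqrt(2 * f[j] * (1 - f[j]))
  }
  if (nrow(x) < k + 1 || ncol(x) < k)
    stop("need more individuals/SNPs than requested components")
  sv <- svd(x, nu = k, nv = 0)
  pcs <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  colnames(pcs) <- paste0("PC", seq_len(k))
  rownames(pcs) <- gm$samples
  pcs
}

#' Kinship matrix from pedigree triples
#'
#' Expected relatedness (numerator relationship matrix A) by the standard
#' tabular recursion: founders have diagonal 1, A[i,j] is the mean of the
#' relationships of j with i's parents. Parents must precede offspring.
#'
#' @param ped data.frame with columns `id`, `father`, `mother` (`NA` or
#'   `"0"` for founders).
#' @return Symmetric relatedness matrix with dimnames `ped$id`.
#' @export
kinship_from_pedigree <- function(ped) {
  n <- nrow(ped)
  id <- as.character(ped$id)
  fa <- match(as.character(ped$father), id)
  mo <- match(as.character(ped$mother), id)
  A <- matrix(0, n, n, dimnames = list(id, id))
  for (i in seq_len(n)) {
    A[i, i] <- 1 + if (!is.na(fa[i]) && !is.na(mo[i]))
      0.5 * A[fa[i], mo[i]] else 0
    if (i > 1) for (j in seq_len(i - 1)) {
      aij <- 0
      if (!is.na(fa[i])) aij <- aij + 0.5 * A[fa[i], j]
      if (!is.na(mo[i])) aij <- aij + 0.5 * A[mo[i], j]
      A[i, j] <- A[j, i] <- aij
    }
  }
  A
}

#' Residualize a trait for familial structure
#'
#' Fits the variance-component model `y = X b + g + e`, `g ~ N(0, sg2 K)`,
#' `e ~ N(0, se2 I)`, by restricted maximum likelihood: the eigendecomposition
#' of `K` reduces the fit to a 1-D optimization of the ratio
#' `delta = sg2 / se2`. Returns `y - X bhat - ghat` where `ghat` is the BLUP
#' of the polygenic term; downstream interaction tests run on these residuals
#' with no further kinship term. With `K = I` this collapses to OLS residuals.
#'
#' @param y trait vector.
#' @param X covariate design matrix (include an intercept).
#' @param K symmetric positive semi-definite relatedness matrix.
#' @return Numeric residual vector with attributes `delta` (variance ratio),
#'   `sigma2_g`, `sigma2_e`.
#' @export
kinship_residualize <- function(y, X, K) {
  n <- length(y)
  X <- as.matrix(X)
  stopifnot(nrow(X) == n, nrow(K) == n, ncol(K) == n)
  if (max(abs(K - t(K))) > 1e-8) stop("K must be symmetric")
  eg <- eigen(K, symmetric = TRUE)
  lam <- eg$values
  if (min(lam) < -1e-6 * max(abs(lam)))
    stop("K is not positive semi-definite within tolerance")
  lam[lam < 0] <- 0
  U <- eg$vectors
  ys <- crossprod(U, y)          # rotated responses
  Xs <- crossprod(U, X)
  p <- qr(X)$rank
  reml_neg <- function(log_delta) {
    d <- exp(log_delta)
    v <- d * lam + 1
    w <- 1 / v
    XtWX <- crossprod(Xs, Xs * w)
    XtWy <- crossprod(Xs, ys * w)
    b <- solve(XtWX, XtWy)
    r <- ys - Xs %*% b
    rss <- sum(w * r^2)
    0.5 * ((n - p) * log(rss / (n - p)) + sum(log(v)) +
             determinant(XtWX, logarithm = TRUE)$modulus)
  }
  opt <- stats::optimize(reml_neg, interval = c(-12, 12))
  d <- exp(opt$minimum)
  # when the likelihood is flat in the ratio (e.g. K = I, where g and e are
  # not separately identifiable) prefer the no-polygenic boundary, which
  # collapses the residuals to OLS
  if (reml_neg(-30) <= opt$objective + 1e-7) d <- exp(-30)
  v <- d * lam + 1
  w <- 1 / v
  XtWX <- crossprod(Xs, Xs * w)
  b <- solve(XtWX, crossprod(Xs, ys * w))
  rs <- ys - Xs %*% b            # rotated marginal residuals
  se2 <- sum(w * rs^2) / (n - p)
  # BLUP of g in rotated space shrinks by d*lam/(d*lam+1); what is left of
  # the marginal residual is rs / (d*lam + 1)
  resid <- drop(U %*% (rs * w))
  structure(resid, delta = d, sigma2_g = d * se2, sigma2_e = se2)
}
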