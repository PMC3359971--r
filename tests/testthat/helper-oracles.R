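# Independent oracles and tiny fixture builders shared across tests.
# These deliberately use different numerical routes than the package
# (normal equations instead of QR, lchoose-based enumeration, etc.).

# OLS via normal equations
oracle_ols <- function(X, y) {
  XtX <- crossprod(X)
  beta <- drop(solve(XtX, crossprod(X, y)))
  res <- y - drop(X %*% beta)
  rss <- sum(res^2)
  df <- nrow(X) - ncol(X)
  se <- sqrt(diag(solve(XtX)) * rss / df)
  list(beta = beta, se = se, rss = rss, df = df)
}

# the full two-model interaction fit, coded independently
oracle_fit_pair <- function(y, C, g1, g2) {
  ok <- !is.na(y) & !is.na(g1) & !is.na(g2) & stats::complete.cases(C)
  y <- y[ok]; C <- as.matrix(C)[ok, , drop = FALSE]
  g1 <- g1[ok]; g2 <- g2[ok]
  x1 <- g1 - 1; z1 <- ifelse(g1 == 1, 0.5, -0.5)
  x2 <- g2 - 1; z2 <- ifelse(g2 == 1, 0.5, -0.5)
  X1 <- cbind(C, x1, z1, x2, z2)
  X2 <- cbind(X1, x1 * x2, x1 * z2, z1 * x2, z1 * z2)
  f1 <- oracle_ols(X1, y); f2 <- oracle_ols(X2, y)
  Fstat <- ((f1$rss - f2$rss) / 4) / (f2$rss / f2$df)
  k <- ncol(C)
  list(coef = f2$beta[(k + 1):(k + 8)], se = f2$se[(k + 1):(k + 8)],
       rss1 = f1$rss, rss2 = f2$rss, df2 = f2$df, F = Fstat,
       p = stats::pf(Fstat, 4, f2$df, lower.tail = FALSE),
       t = f2$beta[(k + 5):(k + 8)] / f2$se[(k + 5):(k + 8)])
}

# exact HWE p by direct enumeration of the conditional het distribution
oracle_hwe_enum <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  na_min <- min(2 * n0 + n1, 2 * n2 + n1)
  hets <- seq(na_min %% 2, na_min, by = 2)
  raw <- vapply(hets, function(h) {
    hom_min <- (na_min - h) / 2
    exp(lchoose(n, hom_min) + lchoose(n - hom_min, h) + h * log(2))
  }, numeric(1))
  prob <- raw / sum(raw)
  obs <- prob[hets == n1]
  sum(prob[prob <= obs * (1 + 1e-12)])
}

# minimal covariate design for simulation-based tests
null_design <- function(n) cbind(intercept = rep(1, n))

# quick genotype vector under HWE
hwe_geno <- function(n, p) stats::rbinom(n, 2, p)

# small VCF text fixture (3 samples, biallelic + one multiallelic record)
write_test_vcf <- function(path, gp = FALSE) {
  fmt <- if (gp) "GT:GP" else "GT"
  body <- if (gp) c(
    "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT:GP\t0/0:0.9,0.1,0.0\t0/1:0.1,0.8,0.1\t1/1:0.1,0.1,0.8",
    "1\t200\trs2\tC\tT\t.\tPASS\t.\tGT:GP\t0/0:0.4,0.4,0.2\t0/0:1,0,0\t0/1:0,1,0"
  ) else c(
    "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "1\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t./.\t0/0\t0/1",
    "1\t300\trs3\tG\tA,C\t.\tPASS\t.\tGT\t0/0\t0/1\t0/2"
  )
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    if (gp) "##FORMAT=<ID=GP,Number=G,Type=Float,Description=\"Posteriors\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           "s1\ts2\ts3"),
    body), path)
  path
}

# geno_matrix literal builder
gm_of <- function(calls, chrom = "1", pos = NULL, ids = NULL) {
  calls <- as.matrix(calls)
  m <- ncol(calls)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  if (is.null(ids)) ids <- paste0("snp", seq_len(m))
  geno_matrix(calls, data.frame(id = ids, chrom = chrom, pos = pos,
                                ref = "A", alt = "B",
                                stringsAsFactors = FALSE))
}
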