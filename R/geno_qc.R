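#' Minor allele frequency of a genotype vector
#'
#' @param g integer vector of calls in `{0, 1, 2, NA}`.
#' @return `min(f, 1 - f)` where `f` is the counted-allele frequency over
#'   non-missing calls.
#' @export
maf <- function(g) {
  g <- g[!is.na(g)]
  if (!length(g)) stop("all calls missing; MAF undefined")
  f <- sum(g) / (2 * length(g))
  min(f, 1 - f)
}

#' Hardy-Weinberg equilibrium test from genotype counts
#'
#' The default is the exact conditional test on the heterozygote count given
#' the allele counts (two-sided: the p-value sums the probabilities of all
#' heterozygote counts whose conditional probability does not exceed that of
#' the observed configuration). This keeps the far tail accurate where the
#' chi-square approximation is unreliable — the regime the genome-wide
#' `P < 1e-6` filter operates in. A 1-df chi-square test (no continuity
#' correction) is available as an option.
#'
#' @param n0,n1,n2 genotype counts (hom, het, hom).
#' @param method `"exact"` (default) or `"chisq"`.
#' @return p-value in `[0, 1]`.
#' @export
hwe_test <- function(n0, n1, n2, method = c("exact", "chisq")) {
  method <- match.arg(method)
  if (any(c(n0, n1, n2) < 0)) stop("genotype counts must be non-negative")
  n <- n0 + n1 + n2
  if (n < 1) stop("need at least one genotyped individual")
  if (method == "chisq") {
    p <- (2 * n0 + n1) / (2 * n)
    e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
    if (any(e == 0)) return(1)
    stat <- sum((c(n0, n1, n2) - e)^2 / e)
    return(stats::pchisq(stat, df = 1, lower.tail = FALSE))
  }
  # exact conditional distribution of the het count given minor-allele count
  na_min <- min(2 * n0 + n1, 2 * n2 + n1)   # minor allele count
  hets <- seq(na_min %% 2, na_min, by = 2)  # feasible heterozygote counts
  # log P(h) up to a constant: 2^h / (n0! n1! n2!) with n1=h,
  # n0=(na_min-h)/2 on the minor side, n2 = n - n1 - n0
  logp <- vapply(hets, function(h) {
    hom_min <- (na_min - h) / 2
    hom_maj <- n - h - hom_min
    h * log(2) - lgamma(hom_min + 1) - lgamma(h + 1) - lgamma(hom_maj + 1)
  }, numeric(1))
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  obs <- prob[match(n1, hets)]
  if (is.na(obs)) stop("heterozygote count inconsistent with allele counts")
  min(1, sum(prob[prob <= obs * (1 + 1e-12)]))
}

#' Composite LD r-squared between two genotype vectors
#'
#' Phase is unknown in hard-call data, so this is the squared Pearson
#' correlation of genotype dosages over jointly non-missing individuals
#' (the standard composite-LD surrogate for haplotype r^2).
#'
#' @param g1,g2 genotype vectors of equal length.
#' @return r^2 in `[0, 1]`.
#' @export
ld_r2 <- function(g1, g2) {
  if (length(g1) != length(g2)) stop("genotype vectors differ in length")
  ok <- !is.na(g1) & !is.na(g2)
  if (sum(ok) < 3) stop("need >= 3 jointly non-missing individuals")
  a <- g1[ok]; b <- g2[ok]
  if (stats::var(a) == 0 || stats::var(b) == 0)
    stop("undefined r2: monomorphic genotype vector")
  stats::cor(a, b)^2
}

#' 3x3 joint genotype table for a SNP pair
#'
#' @param g1,g2 genotype vectors of equal length.
#' @return 3x3 integer matrix, rows = `g1` in 0/1/2, cols = `g2` in 0/1/2,
#'   counted over individuals non-missing at both SNPs.
#' @export
cell_table <- function(g1, g2) {
  if (length(g1) != length(g2)) stop("genotype vectors differ in length")
  ok <- !is.na(g1) & !is.na(g2)
  tab <- table(factor(g1[ok], levels = 0:2), factor(g2[ok], levels = 0:2))
  m <- matrix(as.integer(tab), 3, 3,
              dimnames = list(g1 = 0:2, g2 = 0:2))
  m
}

#' Pair eligibility for interaction testing
#'
#' A SNP pair enters an interaction scan only when every one of the nine
#' genotype-by-genotype cells is strictly larger than `min_cell` (20 in the
#' discovery scan, 10 in validation) and the pairwise LD satisfies
#' `r2 < max_r2`.
#'
#' @param ct 3x3 cell table from [cell_table()].
#' @param r2 composite r^2 from [ld_r2()].
#' @param min_cell strict lower bound on every cell count.
#' @param max_r2 strict upper bound on pairwise r^2 (default 0.1).
#' @return `TRUE`/`FALSE`.
#' @export
pair_eligible <- function(ct, r2, min_cell = 20, max_r2 = 0.1) {
  min(ct) > min_cell && r2 < max_r2
}

#' Hard-call imputed genotypes from posterior probabilities
#'
#' SNPs with imputation info score below `info_min` are dropped outright
#' (typed SNPs, info `NA`, are kept). Remaining calls take the genotype of
#' maximum posterior probability when that maximum reaches `prob_min`, and
#' are missing otherwise.
#'
#' @param post a [geno_posterior()].
#' @param info_min minimum imputation info score (default 0.6).
#' @param prob_min minimum best posterior for a hard call (default 0.8).
#' @return A [geno_matrix()].
#' @export
hard_call <- function(post, info_min = 0.6, prob_min = 0.8) {
  info <- post$variants$info
  keep <- is.na(info) | info >= info_min
  p <- post$p[, keep, , drop = FALSE]
  variants <- post$variants[keep, , drop = FALSE]
  n <- dim(p)[1]; m <- dim(p)[2]
  calls <- matrix(NA_integer_, n, m)
  for (j in seq_len(m)) {
    pj <- p[, j, , drop = TRUE]
    if (n == 1L) pj <- matrix(pj, nrow = 1)
    best <- max.col(pj, ties.method = "first")
    pmax_ <- pj[cbind(seq_len(n), best)]
    calls[, j] <- ifelse(!is.na(pmax_) & pmax_ >= prob_min,
                         best - 1L, NA_integer_)
  }
  geno_matrix(calls, variants, samples = post$samples)
}

#' Remove individuals with excessive missingness
#'
#' @param gm a [geno_matrix()].
#' @param max_missing maximum tolerated missing fraction (default 0.10);
#'   individuals with a missing fraction strictly greater are removed.
#' @return Filtered `geno_matrix`, sample order preserved.
#' @export
filter_individuals <- function(gm, max_missing = 0.10) {
  frac <- rowMeans(is.na(gm$calls))
  keep <- frac <= max_missing
  if (!any(keep)) stop("all individuals removed by missingness filter")
  gm[which(keep), ]
}

#' Per-SNP quality-control filter
#'
#' Removes SNPs with call rate below `min_call_rate`, minor allele frequency
#' less than or equal to `min_maf` (note: MAF exactly at the threshold is
#' removed), or a Hardy-Weinberg test p-value below `hwe_alpha`.
#'
#' @param gm a [geno_matrix()].
#' @param min_call_rate minimum call rate (default 0.90; `< 0.90` removed).
#' @param min_maf MAF threshold (default 0.01; `<= 0.01` removed).
#' @param hwe_alpha HWE p-value threshold (default 1e-6; `< 1e-6` removed).
#' @param hwe_method passed to [hwe_test()].
#' @return Filtered `geno_matrix` with attribute `"qc_report"`: a data.frame
#'   (id, reason) listing removed variants.
#' @export
filter_variants <- function(gm, min_call_rate = 0.90, min_maf = 0.01,
                            hwe_alpha = 1e-6,
                            hwe_method = c("exact", "chisq")) {
  hwe_method <- match.arg(hwe_method)
  m <- nrow(gm$variants)
  reason <- character(0); removed <- character(0)
  keep <- logical(m)
  for (j in seq_len(m)) {
    g <- gm$calls[, j]
    call_rate <- mean(!is.na(g))
    why <- NULL
    if (call_rate < min_call_rate) {
      why <- sprintf("call_rate=%.4f", call_rate)
    } else if (maf(g) <= min_maf) {
      why <- sprintf("maf=%.4f", maf(g))
    } else {
      cnt <- tabulate(g[!is.na(g)] + 1L, nbins = 3L)
      p_hwe <- hwe_test(cnt[1], cnt[2], cnt[3], method = hwe_method)
      if (p_hwe < hwe_alpha) why <- sprintf("hwe_p=%.3g", p_hwe)
    }
    keep[j] <- is.null(why)
    if (!is.null(why)) {
      removed <- c(removed, gm$variants$id[j]); reason <- c(reason, why)
    }
  }
  out <- gm[, which(keep)]
  attr(out, "qc_report") <- data.frame(id = removed, reason = reason,
                                       stringsAsFactors = FALSE)
  out
}

#' Write a tab-delimited QC report
#'
#' @param gm a `geno_matrix` returned by [filter_variants()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(gm, path) {
  rep <- attr(gm, "qc_report")
  if (is.null(rep)) rep <- data.frame(id = character(0),
                                      reason = character(0))
  utils::write.table(rep, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
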