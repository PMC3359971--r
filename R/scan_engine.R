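#' Discovery scan over a candidate pair set
#'
#' Applies the pair eligibility rules (every genotype cell > `min_cell`,
#' pairwise r^2 < `max_r2`), fits the two-locus interaction models for every
#' eligible pair, and Bonferroni-corrects over the pair set's `m` (the
#' number of *planned* tests, before eligibility filtering — so the
#' correction matches the printed test count of a knowledge-driven scan).
#' Output rows are ordered by chromosome and position of the two SNPs.
#'
#' @param pairs a [pair_set()].
#' @param gm cohort [geno_matrix()] (hidden simulated-causal columns are
#'   never tested).
#' @param y trait vector aligned with `gm` samples.
#' @param C covariate design matrix.
#' @param min_cell discovery cell rule (default 20, strict >).
#' @param max_r2 pairwise LD bound (default 0.1).
#' @param m Bonferroni denominator; defaults to `pairs$m`.
#' @return Object of class `scan_result`: `results` (one row per eligible
#'   pair: snp1, snp2, n, coefficients, SEs, F, p, p_c, r2_1, r2_2),
#'   `ineligible` (id pair + reason), `m`.
#' @export
run_scan <- function(pairs, gm, y, C, min_cell = 20, max_r2 = 0.1,
                     m = NULL) {
  stopifnot(inherits(pairs, "pair_set"))
  if (nrow(pairs$pairs) == 0) stop("empty pair set")
  if (is.null(m)) m <- pairs$m
  gm <- visible_variants(gm)
  known <- pairs$pairs$snp1 %in% gm$variants$id &
    pairs$pairs$snp2 %in% gm$variants$id
  if (!any(known)) stop("no pair has both SNPs in the genotype data")
  rows <- list(); inel <- list()
  pp <- pairs$pairs
  for (i in seq_len(nrow(pp))) {
    if (!known[i]) {
      inel[[length(inel) + 1L]] <-
        data.frame(snp1 = pp$snp1[i], snp2 = pp$snp2[i],
                   reason = "absent_from_genotypes",
                   stringsAsFactors = FALSE)
      next
    }
    t <- test_one_pair(y, C, gm, pp$snp1[i], pp$snp2[i], min_cell, max_r2)
    if (!t$eligible) {
      inel[[length(inel) + 1L]] <-
        data.frame(snp1 = t$snp1, snp2 = t$snp2, reason = t$reason,
                   stringsAsFactors = FALSE)
      next
    }
    f <- t$fit
    co <- as.list(f$coef); se <- as.list(f$se)
    names(se) <- paste0("se_", names(se))
    rows[[length(rows) + 1L]] <- cbind(
      data.frame(snp1 = t$snp1, snp2 = t$snp2, n = f$n_complete,
                 stringsAsFactors = FALSE),
      as.data.frame(co), as.data.frame(se),
      data.frame(F = f$F, p = f$p, r2_1 = f$r2_model1, r2_2 = f$r2_model2,
                 r2_pair = t$r2, min_cell = t$min_cell))
  }
  if (!length(rows))
    stop("zero eligible pairs; ineligibility reasons: ",
         paste(names(table(vapply(inel, function(x) x$reason, ""))),
               collapse = ", "))
  res <- do.call(rbind, rows)
  res$p_c <- bonferroni(res$p, m)
  # deterministic ordering by genomic coordinates of both SNPs
  vmap <- gm$variants
  ord_key <- function(id) {
    j <- match(id, vmap$id)
    sprintf("%s:%012d", vmap$chrom[j], vmap$pos[j])
  }
  k1 <- ord_key(res$snp1); k2 <- ord_key(res$snp2)
  swap <- k2 < k1
  tmp <- res$snp1[swap]; res$snp1[swap] <- res$snp2[swap]
  res$snp2[swap] <- tmp
  kk1 <- pmin(k1, k2); kk2 <- pmax(k1, k2)
  res <- res[order(kk1, kk2), , drop = FALSE]
  rownames(res) <- NULL
  ineligible <- if (length(inel)) do.call(rbind, inel) else
    data.frame(snp1 = character(0), snp2 = character(0),
               reason = character(0))
  structure(list(results = res, ineligible = ineligible, m = m),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("interaction scan: %d tested, %d ineligible (m = %s)\n",
              nrow(x$results), nrow(x$ineligible),
              format(x$m, big.mark = ",")))
  top <- x$results[order(x$results$p), ][seq_len(min(5, nrow(x$results))), ]
  print(top[, c("snp1", "snp2", "n", "F", "p", "p_c")], row.names = FALSE)
  invisible(x)
}

#' QQ-plot coordinates for a set of p-values
#'
#' Observed -log10 p against the uniform-order-statistic expectation
#' `-log10((i - 0.5) / m)` (mid-rank convention). No genomic-control
#' deflation is applied.
#'
#' @param pvals p-values in (0, 1].
#' @param m denominator for the expected quantiles; defaults to
#'   `length(pvals)`. Pass the scan's planned test count when the observed
#'   list was eligibility-filtered.
#' @return data.frame with columns `expected`, `observed` (both -log10
#'   scale, ordered from smallest observed p).
#' @export
qq_data <- function(pvals, m = length(pvals)) {
  if (!length(pvals)) stop("no p-values supplied")
  if (any(pvals <= 0 | pvals > 1)) stop("p-values must lie in (0, 1]")
  obs <- sort(pvals)
  data.frame(expected = -log10((seq_along(obs) - 0.5) / m),
             observed = -log10(obs))
}

#' Write scan outputs as tab-delimited text
#'
#' Emits `<prefix>_results.tsv`, `<prefix>_ineligible.tsv` and
#' `<prefix>_qq.tsv` (two-column QQ coordinates).
#'
#' @param scan a [run_scan()] result.
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_scan_results <- function(scan, prefix) {
  stopifnot(inherits(scan, "scan_result"))
  utils::write.table(scan$results, paste0(prefix, "_results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(scan$ineligible, paste0(prefix, "_ineligible.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  qq <- qq_data(scan$results$p, m = scan$m)
  utils::write.table(qq, paste0(prefix, "_qq.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(prefix)
}
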