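# shared worker: eligibility-check then fit one pair; returns a row-like list
test_one_pair <- function(y, C, gm, id1, id2, min_cell, max_r2) {
  g1 <- genotype_of(gm, id1); g2 <- genotype_of(gm, id2)
  ct <- cell_table(g1, g2)
  r2 <- tryCatch(ld_r2(g1, g2), error = function(e) NA_real_)
  out <- list(snp1 = id1, snp2 = id2, min_cell = min(ct), r2 = r2,
              eligible = FALSE, reason = NA_character_, fit = NULL)
  if (is.na(r2)) { out$reason <- "monomorphic"; return(out) }
  if (!pair_eligible(ct, r2, min_cell = min_cell, max_r2 = max_r2)) {
    out$reason <- if (min(ct) <= min_cell)
      sprintf("cell_count=%d", min(ct)) else sprintf("r2=%.3f", r2)
    return(out)
  }
  fit <- tryCatch(fit_pair(y, C, g1, g2), epipair_skip = function(e) e)
  if (inherits(fit, "epipair_skip")) {
    out$reason <- conditionMessage(fit); return(out)
  }
  out$eligible <- TRUE; out$fit <- fit
  out
}

pair_rows <- function(tested) {
  do.call(rbind, lapply(tested, function(t) {
    f <- t$fit
    data.frame(snp1 = t$snp1, snp2 = t$snp2, n = f$n_complete,
               F = f$F, p = f$p, r2_pair = t$r2, min_cell = t$min_cell,
               stringsAsFactors = FALSE)
  }))
}

#' SNPs within a locus window
#'
#' All (non-hidden) variants on the anchor's chromosome strictly closer than
#' `half_width` bp to the anchor position (`|pos - anchor_pos| < half_width`,
#' matching the "each SNP < 200 kb away" rule; the anchor itself is included).
#'
#' @param variants variant data.frame (or a [geno_matrix()]).
#' @param anchor variant id.
#' @param half_width window half-width in bp.
#' @return List of class `locus_window`: `chrom`, `center`, `half_width`,
#'   `snp_ids`.
#' @export
window_snps <- function(variants, anchor, half_width) {
  if (inherits(variants, "geno_matrix")) variants <- variants$variants
  i <- match(anchor, variants$id)
  if (is.na(i)) stop("anchor variant not found: ", anchor)
  vis <- if (is.null(variants$hidden)) rep(TRUE, nrow(variants))
         else !variants$hidden
  hit <- vis & variants$chrom == variants$chrom[i] &
    abs(variants$pos - variants$pos[i]) < half_width
  structure(list(chrom = variants$chrom[i], center = variants$pos[i],
                 half_width = half_width, snp_ids = variants$id[hit]),
            class = "locus_window")
}

# unique unordered id pairs from two id vectors (self-pairs dropped)
cross_pairs <- function(a, b) {
  grid <- expand.grid(s1 = a, s2 = b, stringsAsFactors = FALSE)
  grid <- grid[grid$s1 != grid$s2, , drop = FALSE]
  key <- paste(pmin(grid$s1, grid$s2), pmax(grid$s1, grid$s2), sep = "\r")
  grid[!duplicated(key), , drop = FALSE]
}

run_stage <- function(y, C, gm, pairs, min_cell, max_r2, alpha) {
  tested <- mapply(function(a, b)
    test_one_pair(y, C, gm, a, b, min_cell, max_r2),
    pairs$s1, pairs$s2, SIMPLIFY = FALSE)
  ok <- Filter(function(t) t$eligible, tested)
  n_tests <- length(ok)
  if (n_tests == 0)
    return(list(n_tests = 0L, results = NULL, best = NULL,
                significant = FALSE))
  res <- pair_rows(ok)
  res$p_c <- bonferroni(res$p, n_tests)
  best <- res[which.min(res$p), , drop = FALSE]
  list(n_tests = n_tests, results = res, best = best,
       significant = best$p_c < alpha)
}

#' Adaptive three-stage locus-based validation
#'
#' Attempts to replicate a discovered interaction between anchor SNPs A and B
#' in a validation cohort, allowing the signal to be carried by *different*
#' tag SNPs of the same two loci (tag-LD attenuation): (i) test the anchor
#' pair itself (1 test, raw alpha); (ii) if not significant, test A against
#' every SNP within 200 kb of B and B against every SNP within 200 kb of A
#' (n1 + n2 tests, Bonferroni); (iii) if still not significant, test every
#' SNP within 100 kb of A against every SNP within 100 kb of B (n1 x n2
#' tests, Bonferroni). The procedure stops at the first stage whose best
#' Bonferroni-corrected p-value is below `alpha`. Pairs failing the
#' validation eligibility rule (every cell > `min_cell`, r^2 < `max_r2`) are
#' excluded from testing and from the correction denominator.
#'
#' @param y trait vector (aligned with `gm` samples).
#' @param C covariate design matrix.
#' @param gm cohort [geno_matrix()].
#' @param snpA,snpB anchor variant ids.
#' @param alpha significance level (default 0.05).
#' @param w2 stage-ii window half-width in bp (default 200 kb).
#' @param w3 stage-iii window half-width in bp (default 100 kb).
#' @param min_cell validation cell-count rule (default 10, strict >).
#' @param max_r2 pairwise LD bound (default 0.1).
#' @return Object of class `validation_outcome`: `stage_reached`
#'   (`"i"`, `"ii"`, `"iii"` or `"failed"`), `tests_per_stage`, `best_pair`,
#'   `best_p`, `best_p_c`, per-stage `results`, and `trace` of executed
#'   stages.
#' @export
run_adaptive <- function(y, C, gm, snpA, snpB, alpha = 0.05,
                         w2 = 200e3, w3 = 100e3, min_cell = 10,
                         max_r2 = 0.1) {
  has_a <- snpA %in% gm$variants$id; has_b <- snpB %in% gm$variants$id
  if (!has_a && !has_b)
    return(structure(list(stage_reached = "failed",
                          reason = "both anchors absent",
                          tests_per_stage = c(i = 0L, ii = 0L, iii = 0L),
                          results = list(), trace = character(0)),
                     class = "validation_outcome"))
  if (!has_a || !has_b)
    stop("anchor absent from cohort: ", if (!has_a) snpA else snpB)
  tests <- c(i = 0L, ii = 0L, iii = 0L)
  results <- list(); trace <- character(0)
  finish <- function(stage, st) {
    structure(list(stage_reached = stage, tests_per_stage = tests,
                   best_pair = c(st$best$snp1, st$best$snp2),
                   best_p = st$best$p, best_p_c = st$best$p_c,
                   results = results, trace = trace),
              class = "validation_outcome")
  }
  # stage i: the anchor pair, tested at raw alpha
  trace <- c(trace, "i")
  st1 <- run_stage(y, C, gm, data.frame(s1 = snpA, s2 = snpB,
                                        stringsAsFactors = FALSE),
                   min_cell, max_r2, alpha)
  tests["i"] <- st1$n_tests
  results$i <- st1$results
  if (st1$significant) return(finish("i", st1))
  # stage ii: anchors against the opposite 200 kb windows
  trace <- c(trace, "ii")
  # n1 + n2 planned tests: A against the window around B and B against the
  # window around A (the anchor pair recurs once in each list; the n1 + n2
  # count retains both, so no de-duplication here)
  wA2 <- window_snps(gm, snpA, w2); wB2 <- window_snps(gm, snpB, w2)
  p2 <- rbind(cross_pairs(snpA, wB2$snp_ids), cross_pairs(snpB, wA2$snp_ids))
  st2 <- run_stage(y, C, gm, p2, min_cell, max_r2, alpha)
  tests["ii"] <- st2$n_tests
  results$ii <- st2$results
  if (st2$significant) return(finish("ii", st2))
  # stage iii: full 100 kb window-by-window cross
  trace <- c(trace, "iii")
  wA3 <- window_snps(gm, snpA, w3); wB3 <- window_snps(gm, snpB, w3)
  p3 <- cross_pairs(wA3$snp_ids, wB3$snp_ids)
  st3 <- run_stage(y, C, gm, p3, min_cell, max_r2, alpha)
  tests["iii"] <- st3$n_tests
  results$iii <- st3$results
  if (st3$significant) return(finish("iii", st3))
  best <- if (!is.null(st3$best)) st3$best else
    if (!is.null(st2$best)) st2$best else st1$best
  structure(list(stage_reached = "failed", tests_per_stage = tests,
                 best_pair = if (!is.null(best)) c(best$snp1, best$snp2),
                 best_p = if (!is.null(best)) best$p,
                 best_p_c = if (!is.null(best)) best$p_c,
                 results = results, trace = trace),
            class = "validation_outcome")
}

#' @export
print.validation_outcome <- function(x, ...) {
  cat("adaptive locus-based validation\n")
  cat("  stages executed:", paste(x$trace, collapse = " -> "), "\n")
  cat("  tests per stage: i =", x$tests_per_stage["i"],
      ", ii =", x$tests_per_stage["ii"],
      ", iii =", x$tests_per_stage["iii"], "\n")
  if (x$stage_reached == "failed") {
    cat("  outcome: NOT validated\n")
  } else {
    cat(sprintf("  outcome: validated at stage %s by %s - %s (p = %.3g, p_c = %.3g)\n",
                x$stage_reached, x$best_pair[1], x$best_pair[2],
                x$best_p, x$best_p_c))
  }
  invisible(x)
}

#' Fine mapping around a discovered pair
#'
#' Tests every pair between the two `w`-windows around the anchors (the
#' stage-iii construction applied within the discovery panel) and reports
#' the best pair with a Bonferroni correction over `m_extra` (the discovery
#' scan's test count) plus all fine-mapping pairs tested here.
#'
#' @inheritParams run_adaptive
#' @param w window half-width in bp (default 100 kb).
#' @param m_extra test count already spent (discovery m); default 0.
#' @param min_cell discovery cell rule (default 20).
#' @return List: `best_pair`, `best_p`, `best_p_c`, `n_tests`, `m_total`,
#'   `results` (all tested pairs).
#' @export
fine_map <- function(y, C, gm, snpA, snpB, w = 100e3, m_extra = 0,
                     min_cell = 20, max_r2 = 0.1, alpha = 0.05) {
  wA <- window_snps(gm, snpA, w); wB <- window_snps(gm, snpB, w)
  if (!length(wA$snp_ids) || !length(wB$snp_ids))
    stop("empty fine-mapping window around ",
         if (!length(wA$snp_ids)) snpA else snpB)
  pp <- cross_pairs(wA$snp_ids, wB$snp_ids)
  st <- run_stage(y, C, gm, pp, min_cell, max_r2, alpha)
  if (st$n_tests == 0) stop("no eligible pairs in fine-mapping windows")
  m_total <- m_extra + st$n_tests
  res <- st$results
  res$p_c <- bonferroni(res$p, m_total)
  best <- res[which.min(res$p), , drop = FALSE]
  list(best_pair = c(best$snp1, best$snp2), best_p = best$p,
       best_p_c = best$p_c, n_tests = st$n_tests, m_total = m_total,
       results = res)
}

#' Combine locus-level evidence across validation cohorts
#'
#' Fisher's method on the per-cohort best raw p-values
#' (`X = -2 sum log p ~ chi^2_{2k}`), then a Bonferroni correction over the
#' product of the per-cohort test counts. This is a documented, configurable
#' stand-in for cross-cohort combination; any recipe controlling for the
#' per-cohort search must multiply by at least the realized test counts.
#'
#' @param p_best numeric vector of per-cohort best raw p-values in (0, 1].
#' @param n_tests integer vector of per-cohort test counts.
#' @param correct logical; apply the Bonferroni factor (default TRUE).
#' @return List: `fisher_X`, `df`, `p_combined` (raw), `p_c` (corrected).
#' @export
combine_cohort_evidence <- function(p_best, n_tests, correct = TRUE) {
  if (length(p_best) < 2) stop("need at least two cohorts")
  if (any(p_best <= 0 | p_best > 1)) stop("p-values must lie in (0, 1]")
  stopifnot(length(n_tests) == length(p_best), all(n_tests >= 1))
  X <- -2 * sum(log(p_best))
  df <- 2 * length(p_best)
  p_comb <- stats::pchisq(X, df, lower.tail = FALSE)
  p_c <- if (correct) min(1, p_comb * prod(n_tests)) else p_comb
  list(fisher_X = X, df = df, p_combined = p_comb, p_c = p_c)
}
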