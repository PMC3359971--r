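# window-rich cohort builder: several tags per locus at staggered distances
# and LD, used across the validation tests
window_cohort <- function(n, seed, anchor_r2 = 0.1, window_r2 = 0.9,
                          i_aa = 0.4, sigma_e = 1) {
  spec <- cohort_spec(
    n = n, seed = seed,
    locus1 = locus_spec(0.5, tag_r2 = c(anchor_r2, window_r2, 0.3),
                        chrom = "5", center = 10e6,
                        tag_pos = 10e6 + c(-50e3, 30e3, 80e3), prefix = "A"),
    locus2 = locus_spec(0.5, tag_r2 = c(anchor_r2, window_r2, 0.3),
                        chrom = "15", center = 20e6,
                        tag_pos = 20e6 + c(-40e3, 50e3, 90e3), prefix = "B"),
    effects = effect_spec(i_aa = i_aa, sigma_e = sigma_e))
  sim_cohort(spec)
}

test_that("window membership uses strict distance and excludes hidden columns", {
  coh <- window_cohort(200, seed = 21)
  v <- coh$geno$variants
  w <- window_snps(v, "A_tag1", 200e3)
  expect_setequal(w$snp_ids, c("A_tag1", "A_tag2", "A_tag3"))
  expect_false("A_causal" %in% w$snp_ids)
  # exact boundary: distance == half_width is excluded
  v2 <- data.frame(id = c("a", "in", "out"), chrom = "1",
                   pos = c(1e6, 1e6 + 199999, 1e6 + 200000))
  expect_setequal(window_snps(v2, "a", 2e5)$snp_ids, c("a", "in"))
  # degenerate and empty windows
  expect_equal(window_snps(v2, "a", 0)$snp_ids, character(0))
  v3 <- data.frame(id = c("a", "b"), chrom = c("1", "2"), pos = c(1, 1))
  expect_equal(window_snps(v3, "a", 1e6)$snp_ids, "a")
  expect_error(window_snps(v3, "zz", 1e5), "not found")
})

test_that("stage-iii windows are nested within stage-ii windows", {
  coh <- window_cohort(200, seed = 22)
  w2 <- window_snps(coh$geno, "A_tag1", 200e3)
  w3 <- window_snps(coh$geno, "A_tag1", 100e3)
  expect_true(all(w3$snp_ids %in% w2$snp_ids))
})

test_that("a strong anchor signal stops the procedure at stage i", {
  coh <- window_cohort(3000, seed = 23, anchor_r2 = 1, window_r2 = 0.5,
                       i_aa = 0.5)
  vo <- run_adaptive(coh$y, coh$C, coh$geno, "A_tag1", "B_tag1")
  expect_equal(vo$stage_reached, "i")
  expect_equal(vo$trace, "i")                       # sequential stop
  expect_equal(unname(vo$tests_per_stage), c(1L, 0L, 0L))
  expect_equal(sort(vo$best_pair), c("A_tag1", "B_tag1"))
})

test_that("test counts follow the 1, n1+n2, n1xn2 formulas", {
  coh <- window_cohort(3000, seed = 24, i_aa = 0)    # global null
  vo <- run_adaptive(coh$y, coh$C, coh$geno, "A_tag1", "B_tag1",
                     alpha = 1e-12)                  # force all stages
  # anchors at -50kb/-40kb from center: all 3 tags of the other locus lie
  # within 200 kb of each anchor -> n1 = n2 = 3 at stage ii
  expect_equal(unname(vo$tests_per_stage["i"]), 1L)
  expect_equal(unname(vo$tests_per_stage["ii"]), 6L)
  # 100 kb around A_tag1 (pos -50k): tags at -50k, +30k in range (80k), +80k
  # at 130k out; same around B_tag1 (-40k): -40k, +60k in, +90k out
  expect_equal(unname(vo$tests_per_stage["iii"]), 4L)
  expect_equal(vo$stage_reached, "failed")
  expect_equal(vo$trace, c("i", "ii", "iii"))
})

test_that("tag attenuation defeats stage i but stage iii recovers the signal", {
  hits <- vapply(1:40, function(s) {
    coh <- window_cohort(2500, seed = 1000 + s)
    vo <- run_adaptive(coh$y, coh$C, coh$geno, "A_tag1", "B_tag1")
    c(i = vo$stage_reached == "i", any = vo$stage_reached != "failed")
  }, logical(2))
  expect_lt(mean(hits["i", ]), 0.3)
  expect_gt(mean(hits["any", ]), 0.6)
})

test_that("fine mapping localizes the signal to better-correlated tags", {
  better <- vapply(1:30, function(s) {
    coh <- window_cohort(2500, seed = 2000 + s)
    fm <- fine_map(coh$y, coh$C, coh$geno, "A_tag1", "B_tag1",
                   w = 100e3, m_extra = 0, min_cell = 10)
    gmx <- coh$geno
    r_best <- ld_r2(genotype_of(gmx, fm$best_pair[1]),
                    genotype_of(gmx, if (startsWith(fm$best_pair[1], "A"))
                      "A_causal" else "B_causal"))
    r_anchor <- ld_r2(genotype_of(gmx, "A_tag1"),
                      genotype_of(gmx, "A_causal"))
    r_best > r_anchor
  }, logical(1))
  expect_gt(mean(better), 0.5)
  # windows containing only the anchors reduce to the anchor test
  coh <- window_cohort(2500, seed = 31)
  fm1 <- fine_map(coh$y, coh$C, coh$geno, "A_tag1", "B_tag1", w = 5e3,
                  min_cell = 10)
  expect_equal(fm1$n_tests, 1L)
  expect_setequal(fm1$best_pair, c("A_tag1", "B_tag1"))
  # correction denominator adds the discovery m
  fm2 <- fine_map(coh$y, coh$C, coh$geno, "A_tag1", "B_tag1", w = 5e3,
                  m_extra = 100, min_cell = 10)
  expect_equal(fm2$m_total, 101L)
  expect_equal(fm2$best_p_c, min(1, fm2$best_p * 101))
  # an empty window errors rather than silently falling back
  vsub <- coh$geno[, c("A_tag1", "B_tag1")]
  expect_error(fine_map(coh$y, coh$C, vsub, "A_tag1", "B_tag1", w = 0),
               "empty")
})

test_that("cohort evidence combination follows the chi-square closed form", {
  p <- c(0.01, 0.02, 0.001, 0.05, 0.2)
  out <- combine_cohort_evidence(p, rep(10, 5), correct = FALSE)
  expect_equal(out$fisher_X, -2 * sum(log(p)))
  expect_equal(out$p_combined,
               pchisq(-2 * sum(log(p)), df = 10, lower.tail = FALSE))
  # all ones stay one
  expect_equal(combine_cohort_evidence(c(1, 1, 1), c(5, 5, 5))$p_c, 1)
  # identical small evidence combines to something smaller
  expect_lt(combine_cohort_evidence(c(0.01, 0.01), c(1, 1),
                                    correct = FALSE)$p_combined, 0.01)
  # the Bonferroni factor is the product of test counts
  out2 <- combine_cohort_evidence(c(0.001, 0.002), c(3, 7))
  expect_equal(out2$p_c, min(1, out2$p_combined * 21))
  expect_error(combine_cohort_evidence(c(0, 0.5), c(1, 1)), "0, 1")
  expect_error(combine_cohort_evidence(0.5, 1), "two cohorts")
})
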