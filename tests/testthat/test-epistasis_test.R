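test_that("Cockerham coding and its HWE expectation", {
  cc <- cockerham_code(c(0, 1, 2, NA))
  expect_equal(cc$x, c(-1, 0, 1, NA))
  expect_equal(cc$z, c(-0.5, 0.5, -0.5, NA))
  expect_error(cockerham_code(c(0, 3)), "outside")
  # E[z] = 0 under HWE at allele frequency 0.5
  expect_equal(sum(c(0.25, 0.5, 0.25) * c(-0.5, 0.5, -0.5)), 0)
  set.seed(91)
  z <- cockerham_code(hwe_geno(2e5, 0.5))$z
  expect_lt(abs(mean(z)), 0.01)
})

test_that("fit_pair reproduces an exact noiseless model-(1) construction", {
  set.seed(92)
  n <- 400
  g1 <- hwe_geno(n, 0.5); g2 <- hwe_geno(n, 0.4)
  C <- cbind(intercept = 1, cov = rnorm(n))
  s1 <- cockerham_code(g1); s2 <- cockerham_code(g2)
  y <- 3 + 2 * C[, 2] + 0.7 * s1$x - 0.2 * s1$z + 0.4 * s2$x + 0.1 * s2$z
  f <- fit_pair(y, C, g1, g2)
  expect_lt(max(abs(f$coef[c("i_aa", "i_ad", "i_da", "i_dd")])), 1e-10)
  expect_lt(f$rss2, 1e-16)
  expect_lt(f$rss1, 1e-16)
  expect_equal(unname(f$coef["a1"]), 0.7, tolerance = 1e-10)
})

test_that("fit_pair agrees with the normal-equations oracle on random instances", {
  set.seed(93)
  for (rep in 1:25) {
    n <- 200
    g1 <- hwe_geno(n, runif(1, 0.3, 0.7)); g2 <- hwe_geno(n, runif(1, 0.3, 0.7))
    if (length(unique(g1)) < 3 || length(unique(g2)) < 3) next
    C <- cbind(intercept = 1, c1 = rnorm(n), c2 = rnorm(n), c3 = rbinom(n, 1, 0.4))
    y <- rnorm(n)
    f <- fit_pair(y, C, g1, g2)
    o <- oracle_fit_pair(y, C, g1, g2)
    expect_equal(unname(f$coef), unname(o$coef), tolerance = 1e-8)
    expect_equal(unname(f$se), unname(o$se), tolerance = 1e-8)
    expect_equal(f$F, o$F, tolerance = 1e-8)
    expect_equal(f$p, o$p, tolerance = 1e-8)
    expect_equal(f$rss1, o$rss1, tolerance = 1e-8)
  }
})

test_that("dominance-by-dominance recovery within 2 SE", {
  set.seed(94)
  spec <- cohort_spec(10000, seed = 94,
                      effects = effect_spec(i_dd = 5, sigma_e = 10))
  coh <- sim_cohort(spec)
  g1 <- genotype_of(coh$geno, "A_tag1")   # tag_r2 = 1: tags == causal
  g2 <- genotype_of(coh$geno, "B_tag1")
  f <- fit_pair(coh$y, coh$C, g1, g2)
  expect_lt(abs(f$coef["i_dd"] - 5), 2 * f$se["i_dd"])
})

test_that("interaction F-test arithmetic and degenerate cases", {
  f <- structure(list(rss1 = 110, rss2 = 100, df2 = 1000),
                 class = "interaction_fit")
  ft <- interaction_f_test(f)
  expect_equal(ft$F, 25.0)
  expect_equal(ft$p, pf(25, 4, 1000, lower.tail = FALSE))
  f$rss1 <- f$rss2
  expect_equal(interaction_f_test(f)$F, 0)
  expect_equal(interaction_f_test(f)$p, 1)
  f$rss2 <- 0
  expect_error(interaction_f_test(f), "saturated")
})

test_that("relabeling alleles flips coefficient signs but not F or p", {
  set.seed(95)
  n <- 500
  g1 <- hwe_geno(n, 0.5); g2 <- hwe_geno(n, 0.4)
  C <- cbind(intercept = rep(1, n))
  s1 <- cockerham_code(g1); s2 <- cockerham_code(g2)
  y <- 0.3 * s1$x + 0.2 * s1$x * s2$x + 0.1 * s1$x * s2$z + rnorm(n)
  f <- fit_pair(y, C, g1, g2)
  fr <- fit_pair(y, C, 2 - g1, g2)
  expect_equal(fr$F, f$F, tolerance = 1e-10)
  expect_equal(fr$p, f$p, tolerance = 1e-10)
  expect_equal(unname(fr$coef["a1"]), -unname(f$coef["a1"]), tolerance = 1e-10)
  expect_equal(unname(fr$coef["d1"]), unname(f$coef["d1"]), tolerance = 1e-10)
  expect_equal(unname(fr$coef["i_aa"]), -unname(f$coef["i_aa"]), tolerance = 1e-10)
  expect_equal(unname(fr$coef["i_ad"]), -unname(f$coef["i_ad"]), tolerance = 1e-10)
  expect_equal(unname(fr$coef["i_da"]), unname(f$coef["i_da"]), tolerance = 1e-10)
})

test_that("design columns are orthogonal in expectation at MAF 0.5", {
  set.seed(96)
  n <- 50000
  s1 <- cockerham_code(hwe_geno(n, 0.5))
  s2 <- cockerham_code(hwe_geno(n, 0.5))
  X <- cbind(s1$x, s1$z, s2$x, s2$z, s1$x * s2$x, s1$x * s2$z,
             s1$z * s2$x, s1$z * s2$z)
  X <- scale(X, center = TRUE, scale = FALSE)
  G <- crossprod(X) / n
  offdiag <- G[upper.tri(G)] / sqrt(diag(G)[row(G)[upper.tri(G)]] *
                                    diag(G)[col(G)[upper.tri(G)]])
  expect_lt(max(abs(offdiag)), 0.02)
})

test_that("additive-only 1-df test behaves and beats the 4-df test on pure AxA", {
  set.seed(97)
  n <- 1000
  C <- cbind(intercept = rep(1, n))
  # zero-noise additive trait: interaction coefficient exactly 0
  g1 <- hwe_geno(n, 0.5); g2 <- hwe_geno(n, 0.5)
  y0 <- 0.5 * (g1 - 1) + 0.25 * (g2 - 1)
  expect_lt(abs(additive_only_test(y0, C, g1, g2)$i_aa), 1e-12)
  # power comparison on a pure AxA signal over seeded replicates
  wins <- replicate(60, {
    g1 <- hwe_geno(n, 0.5); g2 <- hwe_geno(n, 0.5)
    y <- 0.15 * (g1 - 1) * (g2 - 1) + rnorm(n)
    a <- additive_only_test(y, C, g1, g2)$p
    b <- fit_pair(y, C, g1, g2)$p
    a < b
  })
  expect_gt(mean(wins), 0.5)
})

test_that("component partition flags the injected component", {
  set.seed(98)
  hits <- replicate(20, {
    spec <- cohort_spec(4000, seed = sample.int(1e6, 1),
                        effects = effect_spec(i_dd = 0.4, sigma_e = 1))
    coh <- sim_cohort(spec)
    f <- fit_pair(coh$y, coh$C,
                  genotype_of(coh$geno, "A_tag1"),
                  genotype_of(coh$geno, "B_tag1"))
    pc <- partition_components(f, alpha = 0.01)
    pc$significant[pc$component == "i_dd"] &&
      sum(pc$significant) <= 2   # i_dd flagged; at most one false positive
  })
  expect_gt(mean(hits), 0.8)
  # t-statistics match the oracle
  spec <- cohort_spec(500, seed = 99, effects = effect_spec(i_dd = 1))
  coh <- sim_cohort(spec)
  g1 <- genotype_of(coh$geno, "A_tag1"); g2 <- genotype_of(coh$geno, "B_tag1")
  f <- fit_pair(coh$y, coh$C, g1, g2)
  pc <- partition_components(f)
  o <- oracle_fit_pair(coh$y, coh$C, g1, g2)
  expect_equal(pc$t, unname(o$t), tolerance = 1e-8)
  # degenerate: zero estimate
  f$coef["i_aa"] <- 0
  pc0 <- partition_components(f)
  expect_equal(pc0$t[pc0$component == "i_aa"], 0)
  expect_equal(pc0$p[pc0$component == "i_aa"], 1)
})

test_that("delta_r2 is the nested-model R2 gap and tracks the planted share", {
  set.seed(100)
  # planted interaction variance share ~0.5%: i_aa chosen so that
  # var(i_aa * x1x2) / var(y) = 0.005 with var(x1x2) = 0.25, sigma_e = 1
  n <- 10000
  i_aa <- sqrt(0.005 / 0.25 / 0.995)
  g1 <- hwe_geno(n, 0.5); g2 <- hwe_geno(n, 0.5)
  y <- i_aa * (g1 - 1) * (g2 - 1) + rnorm(n)
  f <- fit_pair(y, cbind(intercept = rep(1, n)), g1, g2)
  expect_gte(delta_r2(f), 0.003)
  expect_lte(delta_r2(f), 0.008)
  expect_gte(delta_r2(f), 0)
})

test_that("Bonferroni correction caps at one", {
  expect_equal(bonferroni(0.001, 7750), 1.0)
  expect_equal(bonferroni(1.032e-6, 7750), 0.007998, tolerance = 1e-3)
  expect_equal(bonferroni(0.2, 1), 0.2)
  expect_error(bonferroni(1.5, 10))
})

test_that("skip conditions fire for degenerate designs", {
  n <- 50
  C <- cbind(intercept = rep(1, n))
  g1 <- rep(c(0L, 2L), n / 2)           # heterozygote class absent
  g2 <- hwe_geno(n, 0.5)
  y <- rnorm(n)
  expect_error(fit_pair(y, C, g1, g2), class = "epipair_skip")
})
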