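#' Two-SNP haplotype frequencies with a target LD r-squared
#'
#' Solves, in closed form, for the four haplotype frequencies of a tag/causal
#' SNP pair with given allele frequencies and a target haplotype r^2:
#' `D = r * sqrt(p(1-p) q(1-q))` with `r = sign * sqrt(target_r2)`, and
#' frequencies `(pq + D, p(1-q) - D, (1-p)q - D, (1-p)(1-q) + D)` for the
#' (tag, causal) allele combinations (1,1), (1,0), (0,1), (0,0).
#'
#' @param q causal-variant allele-1 frequency.
#' @param p tag-SNP allele-1 frequency.
#' @param target_r2 target r^2 in `[0, 1]`.
#' @param sign sign of D (+1 or -1), i.e. of the tag-causal correlation.
#' @return Named numeric vector `c(h11, h10, h01, h00)` with attribute `r`
#'   (the signed correlation).
#' @export
sim_locus_haplotypes <- function(q, p, target_r2, sign = 1) {
  stopifnot(p > 0, p < 1, q > 0, q < 1,
            target_r2 >= 0, target_r2 <= 1, sign %in% c(-1, 1))
  denom <- sqrt(p * (1 - p) * q * (1 - q))
  d_max <- if (sign > 0) min(p * (1 - q), (1 - p) * q)
           else min(p * q, (1 - p) * (1 - q))
  r2_max <- (d_max / denom)^2
  if (target_r2 > r2_max + 1e-12)
    stop(sprintf("target r2 %.4f infeasible for p=%.3f, q=%.3f (r2max=%.4f)",
                 target_r2, p, q, r2_max))
  r <- sign * sqrt(target_r2)
  D <- r * denom
  h <- c(h11 = p * q + D, h10 = p * (1 - q) - D,
         h01 = (1 - p) * q - D, h00 = (1 - p) * (1 - q) + D)
  h[abs(h) < 1e-15] <- 0
  stopifnot(all(h >= 0), abs(sum(h) - 1) < 1e-12)
  attr(h, "r") <- r
  h
}

#' Specification of one locus: a causal variant plus its tag SNPs
#'
#' @param causal_maf allele-1 frequency of the unobserved causal variant.
#' @param tag_maf allele-1 frequency of each tag (recycled to `n_tags`).
#' @param tag_r2 target haplotype r^2 between each tag and the causal
#'   variant (recycled).
#' @param chrom chromosome label.
#' @param center bp position of the causal variant.
#' @param tag_pos bp positions of the tags; default: evenly spaced within
#'   +/- 90 kb of the causal variant (inside every validation window).
#' @param prefix id prefix for this locus's variants.
#' @return List of class `locus_spec`.
#' @export
locus_spec <- function(causal_maf = 0.5, tag_maf = causal_maf, tag_r2 = 1,
                       chrom = "1", center = 10e6, tag_pos = NULL,
                       prefix = "L") {
  k <- max(length(tag_maf), length(tag_r2))
  tag_maf <- rep_len(tag_maf, k); tag_r2 <- rep_len(tag_r2, k)
  if (is.null(tag_pos)) {
    tag_pos <- if (k == 1) center + 1000
               else round(center + seq(-90e3, 90e3, length.out = k))
  }
  stopifnot(length(tag_pos) == k)
  structure(list(causal_maf = causal_maf, tag_maf = tag_maf,
                 tag_r2 = tag_r2, chrom = as.character(chrom),
                 center = center, tag_pos = tag_pos, prefix = prefix),
            class = "locus_spec")
}

#' Specification of the interaction effects generating a phenotype
#'
#' Effects act on the Cockerham scores of the *causal* variants; tags pick
#' up attenuated versions through LD. Defaults are a pure-null trait on a
#' standardized scale (residual sd 1) with modest covariate effects.
#'
#' @param a1,d1,a2,d2 marginal additive/dominance effects at the causal loci.
#' @param i_aa,i_ad,i_da,i_dd interaction effects.
#' @param intercept trait intercept.
#' @param beta_sex,beta_age,beta_age2,beta_bmi covariate effects.
#' @param sigma_e residual sd (> 0).
#' @param sigma_g sd of the polygenic term (used when a kinship matrix is
#'   supplied to [sim_phenotype()]).
#' @return List of class `effect_spec`.
#' @export
effect_spec <- function(a1 = 0, d1 = 0, a2 = 0, d2 = 0,
                        i_aa = 0, i_ad = 0, i_da = 0, i_dd = 0,
                        intercept = 0, beta_sex = 0.2, beta_age = 0.01,
                        beta_age2 = 0, beta_bmi = 0.02,
                        sigma_e = 1, sigma_g = 0) {
  stopifnot(sigma_e > 0, sigma_g >= 0)
  structure(as.list(environment()), class = "effect_spec")
}

#' Specification of one simulated cohort
#'
#' @param n number of individuals.
#' @param locus1,locus2 [locus_spec()] objects; the two loci are unlinked
#'   (inter-locus LD zero), mimicking interacting loci on different
#'   chromosomes.
#' @param effects an [effect_spec()].
#' @param seed integer seed recorded in the spec; all generators draw from it.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n, locus1 = locus_spec(chrom = "5", prefix = "A"),
                        locus2 = locus_spec(chrom = "15", prefix = "B"),
                        effects = effect_spec(), seed = 1L) {
  stopifnot(n >= 1)
  structure(list(n = n, locus1 = locus1, locus2 = locus2,
                 effects = effects, seed = as.integer(seed)),
            class = "cohort_spec")
}

# draw 2n haplotypes for one locus; returns genotype columns (causal first)
sim_locus_genotypes <- function(ls, n) {
  k <- length(ls$tag_maf)
  hap_causal <- matrix(stats::rbinom(2 * n, 1, ls$causal_maf), ncol = 2)
  g <- matrix(0L, n, k + 1L)
  g[, 1] <- as.integer(rowSums(hap_causal))
  for (t in seq_len(k)) {
    h <- sim_locus_haplotypes(ls$causal_maf, ls$tag_maf[t], ls$tag_r2[t])
    p_given1 <- h["h11"] / ls$causal_maf          # P(tag=1 | causal=1)
    p_given0 <- h["h10"] / (1 - ls$causal_maf)
    pr <- ifelse(hap_causal == 1, p_given1, p_given0)
    hap_tag <- matrix(stats::rbinom(2 * n, 1, pr), ncol = 2)
    g[, t + 1L] <- as.integer(rowSums(hap_tag))
  }
  variants <- data.frame(
    id = c(paste0(ls$prefix, "_causal"),
           paste0(ls$prefix, "_tag", seq_len(k))),
    chrom = ls$chrom,
    pos = c(ls$center, ls$tag_pos),
    ref = "A", alt = "B",
    hidden = c(TRUE, rep(FALSE, k)),
    stringsAsFactors = FALSE)
  list(calls = g, variants = variants)
}

#' Simulate genotypes for a two-locus cohort
#'
#' Individuals are formed by two independent haplotype draws per locus
#' (random mating, hence HWE at every variant); each tag haplotype allele is
#' drawn conditionally on the causal allele so that the realized tag-causal
#' r^2 matches its target. Causal columns are retained but flagged `hidden`
#' so scans never see them ([visible_variants()]).
#'
#' @param spec a [cohort_spec()].
#' @return A [geno_matrix()] with hidden causal columns `A_causal`,
#'   `B_causal` and visible tags `A_tag*`, `B_tag*`.
#' @export
sim_genotypes <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  l1 <- sim_locus_genotypes(spec$locus1, spec$n)
  l2 <- sim_locus_genotypes(spec$locus2, spec$n)
  geno_matrix(cbind(l1$calls, l2$calls),
              rbind(l1$variants, l2$variants),
              samples = sprintf("ind%05d", seq_len(spec$n)))
}

#' Simulate covariates (sex, age, BMI)
#'
#' Sex is Bernoulli(0.5); age ~ N(54, 5.7^2) years; BMI ~ N(27, 4.8^2)
#' kg/m^2 — magnitudes typical of middle-aged epidemiological cohorts.
#'
#' @param n number of individuals.
#' @return data.frame with columns sex, age, age2, bmi.
#' @export
sim_covariates <- function(n) {
  age <- stats::rnorm(n, 54, 5.7)
  data.frame(sex = stats::rbinom(n, 1, 0.5), age = age, age2 = age^2,
             bmi = stats::rnorm(n, 27, 4.8))
}

#' Simulate a phenotype from causal-locus Cockerham effects
#'
#' `y = intercept + covariate effects + a/d terms and the four interaction
#' products at the CAUSAL variants + optional polygenic term (sigma_g^2 K)
#' + N(0, sigma_e^2)` noise.
#'
#' @param gm a [geno_matrix()] from [sim_genotypes()] (hidden causal columns
#'   present).
#' @param effects an [effect_spec()].
#' @param K optional kinship/relatedness matrix for the polygenic term.
#' @param seed optional seed (defaults to leaving the RNG stream alone, so
#'   callers can chain draws deterministically).
#' @return List: `y` (trait vector), `covar` (data.frame), `C` (covariate
#'   design matrix with intercept).
#' @export
sim_phenotype <- function(gm, effects, K = NULL, seed = NULL) {
  stopifnot(inherits(effects, "effect_spec"))
  if (!is.null(seed)) set.seed(seed)
  n <- length(gm$samples)
  causal_ids <- gm$variants$id[gm$variants$hidden]
  if (length(causal_ids) != 2)
    stop("expected exactly two hidden causal variants")
  s1 <- cockerham_code(genotype_of(gm, causal_ids[1]))
  s2 <- cockerham_code(genotype_of(gm, causal_ids[2]))
  covar <- sim_covariates(n)
  C <- cbind(intercept = 1, sex = covar$sex, age = covar$age,
             age2 = covar$age2, bmi = covar$bmi)
  e <- effects
  y <- e$intercept + e$beta_sex * covar$sex + e$beta_age * covar$age +
    e$beta_age2 * covar$age2 + e$beta_bmi * covar$bmi +
    e$a1 * s1$x + e$d1 * s1$z + e$a2 * s2$x + e$d2 * s2$z +
    e$i_aa * s1$x * s2$x + e$i_ad * s1$x * s2$z +
    e$i_da * s1$z * s2$x + e$i_dd * s1$z * s2$z +
    stats::rnorm(n, 0, e$sigma_e)
  if (!is.null(K) && e$sigma_g > 0) {
    L <- chol(K + diag(1e-8, n))
    y <- y + e$sigma_g * drop(crossprod(L, stats::rnorm(n)))
  }
  list(y = y, covar = covar, C = C)
}

#' Simulate a full cohort (genotypes + phenotype)
#'
#' @param spec a [cohort_spec()].
#' @param K optional kinship matrix.
#' @return List: `geno` ([geno_matrix()]), `y`, `covar`, `C`.
#' @export
sim_cohort <- function(spec, K = NULL) {
  gm <- sim_genotypes(spec)         # sets the RNG from spec$seed
  ph <- sim_phenotype(gm, spec$effects, K = K)  # continues the stream
  list(geno = gm, y = ph$y, covar = ph$covar, C = ph$C)
}

#' Expected tag-level additive-by-additive interaction effect
#'
#' The interaction effect observed at two tag SNPs is the causal interaction
#' effect attenuated by the product of the two tag-causal LD correlations;
#' with equal tag and causal allele frequencies the A x A attenuation factor
#' is exactly `r1 * r2`.
#'
#' @param causal_effect causal-scale i_aa.
#' @param r1,r2 tag-causal correlations (signed r, not r^2) at the two loci.
#' @return `causal_effect * r1 * r2`.
#' @export
expected_tag_attenuation <- function(causal_effect, r1, r2) {
  stopifnot(abs(r1) <= 1, abs(r2) <= 1)
  causal_effect * r1 * r2
}

#' Simulate background genotypes for two diverged subpopulations
#'
#' Each SNP's allele frequency differs by `divergence` between the two
#' subpopulations (clipped to [0.05, 0.95]); used to exercise PCA-based
#' stratification correction.
#'
#' @param n1,n2 individuals in each subpopulation.
#' @param m number of SNPs.
#' @param divergence absolute allele-frequency difference (default 0.2).
#' @return A [geno_matrix()]; sample order is subpopulation 1 then 2, with
#'   attribute `"pop"` giving the labels.
#' @export
sim_structured_genotypes <- function(n1, n2, m, divergence = 0.2) {
  p1 <- stats::runif(m, 0.2, 0.8)
  p2 <- pmin(0.95, pmax(0.05, p1 + sample(c(-1, 1), m, TRUE) * divergence))
  calls <- rbind(
    sapply(p1, function(p) stats::rbinom(n1, 2, p)),
    sapply(p2, function(p) stats::rbinom(n2, 2, p)))
  variants <- data.frame(id = paste0("bg", seq_len(m)), chrom = "1",
                         pos = seq_len(m) * 1000L, ref = "A", alt = "B",
                         stringsAsFactors = FALSE)
  gm <- geno_matrix(calls, variants)
  attr(gm, "pop") <- rep(c(1L, 2L), c(n1, n2))
  gm
}

#' Sibling-block relatedness matrix
#'
#' Block-diagonal expected-relatedness matrix: diagonal 1, siblings within a
#' block 0.5, zero across blocks.
#'
#' @param n number of individuals (a multiple of `block`).
#' @param block sibship size (default 2).
#' @return n x n numeric matrix.
#' @export
sim_sibling_kinship <- function(n, block = 2) {
  stopifnot(n %% block == 0)
  b <- matrix(0.5, block, block); diag(b) <- 1
  K <- matrix(0, n, n)
  for (i in seq_len(n / block)) {
    idx <- ((i - 1) * block + 1):(i * block)
    K[idx, idx] <- b
  }
  K
}
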