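---
title: "Detecting and validating SNP-SNP interactions with epipair"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and validating SNP-SNP interactions with epipair}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epipair)
```

## The problem

Genome-wide association studies of quantitative lipid traits (TC, LDL-C,
HDL-C, log-TG) have catalogued many loci with individually small additive
effects. Statistical epistasis — a two-locus genotype effect that deviates
from the sum of the single-locus additive and dominance effects — is one
candidate source of the unexplained heritable variation, but an exhaustive
pairwise scan over millions of SNPs entails trillions of tests, and the
multiple-testing burden destroys power. `epipair` implements the two
strategies that make such an analysis feasible:

1. **Knowledge-driven candidate restriction.** Only pairs drawn from prior
   knowledge are tested: all pairs among established GWAS-hit SNPs, cross-gene
   pairs from a protein-protein-interaction list, or all pairs within a
   pathway gene set, with SNPs assigned to genes using a ±5 kb positional
   flank.
2. **Locus-based validation.** A genotyped tag SNP is usually only in partial
   LD with the underlying causal variant, and the interaction effect observed
   at two tags is attenuated by the *product* of the two tag-causal LD
   coefficients. Different genotyping platforms tag the same causal variants
   through different SNPs, so replication of the original SNP *pair* in
   another cohort can fail even when the locus-level interaction is real. The
   adaptive three-stage procedure widens the search from the anchor pair to
   the surrounding loci only as far as needed.

## The interaction model

For genotypes $G_i \in \{0, 1, 2\}$ (copies of the counted allele at SNP
$i$), each SNP is given an orthogonal Cockerham coding: an additive score
$x_i = G_i - 1 \in \{-1, 0, 1\}$ and a dominance score $z_i$ equal to $+1/2$
for heterozygotes and $-1/2$ for homozygotes. Two nested linear models are
fitted by OLS with covariates $C$ (intercept, sex, age, age², BMI, plate
indicators where available, top-10 genotype PCs):

$$\text{(1)}\quad y = C\beta_0 + a_1 x_1 + d_1 z_1 + a_2 x_2 + d_2 z_2 + \varepsilon$$

$$\text{(2)}\quad y = \text{(1)} + i_{aa} x_1 x_2 + i_{ad} x_1 z_2 + i_{da} z_1 x_2 + i_{dd} z_1 z_2 + \varepsilon$$

The omnibus interaction test is the 4-df F-test
$F = \frac{(RSS_1 - RSS_2)/4}{RSS_2 / df_2}$, which is sensitive to any of
the four interaction forms (additive×additive, additive×dominance,
dominance×additive, dominance×dominance). The four components are also
estimated and tested individually with t-tests (df $= df_2$), which is how
interaction *patterns* are compared across cohorts, and the variance
explained by interaction is reported as $R^2_{(2)} - R^2_{(1)}$. A 1-df
additive-only variant (`additive_only_test()`, the PLINK `--epistasis`
analogue) is provided for comparison.

The exact indicator values of the coding are a convention: any affine
reparameterization yields the identical F-test (asserted by the
allele-relabeling invariance tests). Component estimates do depend on it,
and the $\{-1,0,1\} \times \{\pm 1/2\}$ choice is used because it renders
the eight design columns mutually orthogonal in expectation under HWE with
allele frequency 1/2, which makes the component partition interpretable.

## Quality control and eligibility

Defaults follow standard practice for this analysis type: individuals with
more than 10% missing genotypes are removed; SNPs with call rate below 90%,
MAF ≤ 1% (note the boundary is removed), or HWE test $P < 10^{-6}$ are
removed. The HWE test is by default the *exact* conditional test on the
heterozygote count given allele counts (two-sided, summing configurations no
more probable than the observed one): at a $10^{-6}$ threshold the decision
is made deep in the tail, where the chi-square approximation is unreliable.
A chi-square option is provided. One consequence worth knowing: with $n$
individuals the smallest attainable HWE p-value is bounded below
(approximately the chi-square bound $P(\chi^2_1 > n)$), so tiny samples can
never fail this filter — at $n = 20$ no SNP is removable at $10^{-6}$.

A *pair* enters a scan only when (i) all nine genotype-by-genotype cells
hold strictly more than 20 individuals (discovery) or 10 (validation), and
(ii) the pairwise LD satisfies $r^2 < 0.1$, so that an apparent interaction
cannot be a haplotype main effect in disguise. Since phase is unknown in
hard-call data, $r^2$ is the composite (genotype-dosage correlation)
estimate, computed within the analysis cohort. Both thresholds are strict
inequalities, and pairs are analyzed complete-case over the two SNPs,
phenotype and covariates; if complete-casing empties a genotype class, the
pair is skipped with a logged reason rather than fitted rank-deficient.

Imputed genotypes are consumed as posterior triples: SNPs with imputation
info score < 0.6 are dropped, and calls are made at the maximum-posterior
genotype only when that posterior reaches 0.8 (missing otherwise).

## Phenotype preparation

Traits measured at multiple visits are averaged per individual (as are age
and BMI); the averaged age is then squared for the age² covariate
(square-of-average, not average-of-squares). TG is log-transformed with the
natural log — the base is a convention with no effect on inference.
Individuals *known* to take lipid-lowering medication are excluded; a
missing flag means not medicated. Plate is included as a categorical
covariate only when a plate column is present.

Population structure is handled by including the top-10 PCs of the
column-standardized genotype matrix (missing genotypes mean-imputed,
columns scaled by $\sqrt{2f(1-f)}$) as covariates. Family structure is
handled in two stages: the variance-component model
$y = X\beta + g + e$, $g \sim N(0, \sigma_g^2 K)$, is fitted by REML (the
eigendecomposition of $K$ reduces the fit to a 1-D search over
$\delta = \sigma_g^2/\sigma_e^2$), and all interaction tests are then run on
the residuals $y - X\hat\beta - \hat g$ with no further kinship term.
Refitting the mixed model per SNP pair would be statistically slightly
sharper but orders of magnitude slower; the two-stage route is the
procedure this package commits to. When the likelihood is flat in $\delta$
(e.g. $K = I$, where $g$ and $e$ are not separately identifiable) the
no-polygenic boundary is preferred, so the residuals collapse to OLS
residuals.

## Candidate pairs and multiple-testing accounting

`pairs_from_hits()` generates all $n(n-1)/2$ unordered pairs of a hit list
(125 hits → 7,750 pairs). `pairs_from_gene_pairs()` crosses the SNP lists
of each gene pair ($n_1 \times n_2$ tests), removing self-pairs and
de-duplicating pairs repeated across overlapping gene pairs;
`pairs_from_gene_set()` takes all pairs among the union of SNPs mapped to a
gene set. SNP-to-gene mapping is purely positional
($\text{start} - 5\,\text{kb} \le \text{pos} \le \text{end} + 5\,\text{kb}$,
inclusive, strand ignored).

The Bonferroni denominator $m$ is the number of *generated* pairs, before
per-cohort eligibility filtering — the planned-test count a reader can
verify from the candidate lists — and is configurable to post-filter
counting. De-duplication means a raw cross-product count (`n_raw`) can
exceed $m$; both are reported.

## The adaptive validation procedure

Given anchors A and B discovered elsewhere, `run_adaptive()` runs, in a
validation cohort:

* **Stage i** — the anchor pair alone, at raw $\alpha$ (1 test);
* **Stage ii** — A against every SNP within 200 kb of B, and B against every
  SNP within 200 kb of A ($n_1 + n_2$ tests, Bonferroni). The anchor pair
  occurs in both lists and both occurrences are counted, keeping the
  denominator at the planned $n_1 + n_2$;
* **Stage iii** — every SNP within 100 kb of A against every SNP within
  100 kb of B ($n_1 \times n_2$ tests, Bonferroni).

Windows are half-width readings of "the X kb surrounding": strictly less
than the half-width from the anchor position, anchors included, on the same
chromosome. The procedure stops at the first stage whose best corrected
p-value clears $\alpha$; the same $\alpha$ is used at every stage (no
splitting), so the family-wise error of the full sequence is bounded by
$3\alpha$ and in practice sits well below it because each stage is
Bonferroni-conservative and the stage tests are correlated. Pairs failing
the validation eligibility rule (cells > 10, $r^2 < 0.1$) are excluded from
both testing and the denominator. `fine_map()` applies the stage-iii
construction inside the discovery panel, correcting over the discovery scan
count *plus* all fine-mapping pairs.

Cross-cohort evidence is combined by Fisher's method on the per-cohort best
raw p-values followed by a Bonferroni factor equal to the product of the
per-cohort test counts. This recipe is a documented, configurable choice —
several defensible recipes exist — and is deliberately conservative. Note
Fisher's combination is only guaranteed to sharpen *small* p-values; for
p-values near 1 the combined value can exceed the marginals.

## The synthetic-data generator

Because the cohort data this analysis is designed for are access-restricted,
every procedure is exercised on synthetic cohorts that reproduce the
statistical structure the method assumes:

* **Genotypes.** Each locus is an unobserved causal variant plus one or more
  tag SNPs. Haplotype frequencies realizing a target tag-causal $r^2$ are
  solved in closed form from $D = r\sqrt{p(1-p)q(1-q)}$; individuals are two
  independent haplotype draws (random mating, hence HWE), with each tag
  allele drawn conditionally on the causal allele. The two interacting loci
  are unlinked (inter-locus LD 0), mirroring an interaction between loci on
  different chromosomes; linked-locus simulation is out of scope. Causal
  columns are carried in the genotype matrix but flagged hidden, and scans
  structurally cannot see them.
* **Phenotypes.** $y$ = intercept + covariate effects + Cockerham terms *at
  the causal loci* + optional polygenic term $N(0, \sigma_g^2 K)$ + Gaussian
  noise. Defaults describe a standardized trait: $\sigma_e = 1$, all genetic
  effects 0, covariate effects (sex 0.2, age 0.01/yr, BMI 0.02 per kg/m²)
  of realistic relative magnitude, age ~ N(54, 5.7²) years and BMI ~
  N(27, 4.8²) kg/m² as in middle-aged epidemiological cohorts, sex
  Bernoulli(1/2).
* **Attenuation oracle.** For the additive×additive component with equal tag
  and causal allele frequencies, the expected tag-level effect is exactly
  the causal effect times $r_1 r_2$ (`expected_tag_attenuation()`); with
  $r_1 = r_2 = 0.7$ the observed effect is ~0.49 of the causal one, the
  quadratic loss that motivates locus-based validation. Dominance-component
  attenuation involves higher moments and is verified empirically rather
  than by closed form.
* **Auxiliary structure.** Two-subpopulation allele-frequency divergence
  (for the PCA tests), sibling-block kinship matrices and pedigree-derived
  relatedness (for the REML tests). Tag positions default to even spacing
  within ±90 kb of the causal variant so that validation windows are
  populated; the spacing is arbitrary and tests that depend on distances set
  positions explicitly.

What a green simulation-based test does *not* establish: realism of
coalescent haplotype diversity, allele-frequency spectra, genotyping error,
or imputation-posterior miscalibration — the generator draws clean HWE
genotypes with exactly the specified LD. The tests establish the
*statistical* contracts: calibration of the F-test under the null,
unbiased component recovery, the attenuation law, and the error control and
power ordering of the three-stage procedure.

## Numerical choices and edge cases

* OLS is by QR decomposition; the test suite cross-checks coefficients, SEs,
  F and p against an independent normal-equations implementation to 1e-8.
* `interaction_f_test()` refuses saturated fits (RSS₂ = 0) rather than
  returning an infinite F.
* Exact-HWE p-values compare configuration probabilities with a relative
  tolerance of 1e-12 so that ties (e.g. the perfect-HWE mode) are included,
  making the perfect-proportion case return exactly 1.
* Rank-deficient pair designs raise a classed condition (`epipair_skip`)
  that scan loops convert into a logged ineligibility record.
* Multi-allelic VCF records are skipped with a warning; only biallelic SNPs
  are analyzed. PLINK `.bed` I/O is SNP-major with the standard 2-bit
  encoding; missing calls round-trip.
* QQ expected quantiles use the mid-rank convention $-\log_{10}((i-0.5)/m)$;
  no genomic-control deflation is applied.
* Seeds: every generator is deterministic given (spec, seed); scan output
  ordering is by chromosome and position, so re-runs are byte-identical.

## Known limitations

Binary traits (logistic interaction), more-than-two-locus models, chrX and
haploid genotypes, phasing, genotype imputation itself, and
kinship-estimation from genome-wide markers are out of scope. The
cross-cohort combination recipe is one defensible choice among several. The
eligibility r² is computed within-cohort; a reference-panel option is not
provided.
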