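---
title: "Models and methods behind admixqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind admixqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`admixqtl` studies how genetic ancestry shapes the genetic architecture
of gene expression in admixed cohorts. It provides, as one coherent
pipeline: a synthetic admixed-cohort generator with labeled ground
truth; unconstrained REML estimation of cis-heritability ($h^2$) and
genetic variance ($V_G$); a stepwise global/local ancestry association
procedure; FastQTL-style cis-eQTL mapping with beta-approximated
permutation calibration; single-causal-variant fine-mapping with 95%
credible sets; a tiered classifier of ancestry-specific eQTLs
(anc-eQTLs); and elastic-net transcriptome prediction with
summary-statistic TWAS. Real cohorts of this kind are access-controlled,
so every stage is exercised end-to-end on simulated data whose causal
structure is known exactly.

# The synthetic cohort

## Ancestral allele frequencies

Ancestral populations (by default two, labeled AFR-like and EUR-like)
receive per-variant allele frequencies from the Balding–Nichols model:
given a base frequency $p_0 \sim U(0.05, 0.95)$ and differentiation
parameter $F$, each population draws
$p_k \sim \mathrm{Beta}\big(p_0 \tfrac{1-F}{F},\,(1-p_0)\tfrac{1-F}{F}\big)$.
The default $F = 0.15$ is in the range typically estimated between
continental human populations. As $F \to 0$ all populations collapse
onto $p_0$; the test suite verifies the realized differentiation against
an independent Hudson-estimator $F_{ST}$ oracle.

A fraction of variants (default 8% of each cis-region) is forced to be
**population-private**: common in exactly one ancestry with frequency
$U(0.05, 0.15)$, and essentially absent elsewhere ($U(0, 0.002)$).
These are the substrate for allele-frequency-driven (tier-1)
ancestry-specific eQTLs. The owner-ancestry frequency range mirrors the
MAFs observed for exemplar tier-1 anc-eQTLs (on the order of 0.05–0.1
in the high-ancestry group and $\le 0.002$ in the low group); with a
residual ~3% admixture in the low-ancestry group, a variant at the top
of this range still realizes a low-group MAF below the 0.01 rarity
threshold with high probability, so the planted labels remain
consistent with the framework's own MAF definition.

## Haplotypes, LD, and local ancestry

Each gene occupies its own cis-region; regions are spaced so that
±1 Mb windows never overlap. Within a region variants are grouped into
LD blocks (default 20 variants). For each gene and haplotype, a local
ancestry is drawn from the individual's global ancestry proportions
$\theta$; the haplotype's alleles are then drawn from that ancestry's
frequencies through a Gaussian copula with block-wise latent
correlation $\rho_k$ that can differ between ancestries. Dosage is the
sum of the two haplotypes, so dosage, haplotypes and the local ancestry
allele count at the TSS (0/1/2) are mutually consistent by
construction. Local ancestry is simulated per gene (a single cis-block
ancestry per haplotype) rather than as chromosome-length tracts,
because all downstream analyses use only ancestry at the TSS.

Global ancestry proportions are Beta/Dirichlet distributed. The default
two-group study draws a high-ancestry group around $\theta = 0.8$ and a
low-ancestry group around $\theta = 0.03$ (concentration 40), matching
the median global ancestries reported for admixed American cohorts;
analysis groups are then re-derived from the realized $\theta$ with the
standard cut-offs (high $> 0.5$, low $< 0.1$).

## Expression scenarios

Expression is simulated as a causal genetic value plus optional
covariate effects plus Gaussian noise, scaled so the genetic component
explains a target $h^2$ of a unit-variance trait
($V_G = 2p(1-p)\beta^2$ for a single causal variant; the generator uses
the realized dosage variance, which also absorbs admixture-induced
departures from Hardy–Weinberg). Five labeled scenarios are available:

* **shared** — one causal variant, common in every ancestry, identical
  effect everywhere;
* **tier1** — causal variant population-private to the high-diversity
  ancestry (allele-frequency-driven specificity);
* **tier2** — causal variant common in both ancestries but *not typed*
  in the genotyping panel handed to analysis, inside a block whose
  copula correlation is high (0.9) in the high-diversity ancestry and
  low (0.05) elsewhere: its typed tags carry the signal in one ancestry
  only (LD-driven specificity). Masking the causal site is what makes
  nonoverlapping credible sets possible when the underlying biology is
  shared — an untyped causal variant is the canonical mechanism behind
  LD-driven cross-population differences;
* **tier3** — same causal variant everywhere, but the allelic effect
  depends on the ancestry of the carrying haplotype (default ratio 2),
  producing genuine effect-size heterogeneity;
* **null** — no genetic effect.

Covariates (age uniform on 8–21 years, sex and asthma status
Bernoulli(0.5)) mirror a pediatric asthma case–control cohort; their
effects on expression default to zero but are configurable.

All randomness flows from a single seed through named streams, so each
stage is reproducible in isolation.

## What the generator does not emulate

Realistic recombination maps and chromosome-scale ancestry tracts,
phasing error, sequencing/quantification noise, polygenic cis
architecture (more than one causal variant per gene), rare-variant
effects, and gene–environment interaction. Consequently, passing the
benchmarks demonstrates that each statistical stage is correct and
calibrated under its own assumptions — not that those assumptions hold
in any particular real cohort.

# Heritability

Cis-kinships are built from variants within the gene's region passing
MAF ≥ 0.01, either as the standardized GRM $K = XX^\top/m$ with columns
$(g - 2p)/\sqrt{2p(1-p)}$, or after LDAK-Thin-style duplicate-tag
pruning ($r^2 > 0.98$ within 100 kb). REML is **unconstrained**:
$\hat\sigma^2_g$ (and hence $\hat h^2 = \hat\sigma^2_g /
(\hat\sigma^2_g + \hat\sigma^2_e)$) may be negative, which keeps group
medians unbiased near the boundary; downstream summaries use medians.

Single-kinship fits use an exact eigendecomposition profile: after
rotating by the eigenvectors of $K$ the restricted likelihood is a
one-dimensional function of $\lambda = \sigma^2_g/\sigma^2_e$,
maximized by a coarse grid followed by Brent refinement over
$\lambda \in (-1/d_{\max}, \infty)$ (the full unconstrained
positive-definite region). Multi-kinship fits (MAF-bin partitioning,
default bins 0.01–0.10 and 0.1–0.5) use average-information REML with
step-halving whenever an update would leave the positive-definite
region, converging on a relative log-likelihood change of $10^{-6}$
(max 100 iterations); non-convergence is flagged, not thrown. A
kinship proportional to the identity makes the two components
unidentifiable and is flagged directly. The likelihood-ratio test of
$\sigma^2_g = 0$ uses the boundary mixture
$\tfrac12\chi^2_0 + \tfrac12\chi^2_1$. Group contrasts use the
two-sided Wilcoxon rank-sum test (normal approximation with tie
correction).

# Ancestry association

The stepwise procedure is implemented literally as a residual-on-
residual cascade: inverse-normalized expression is regressed on age,
sex and asthma (model 0); model-0 residuals on global ancestry
(model 1); model-1 residuals on the local ancestry allele count at the
TSS (model 2), with Benjamini–Hochberg FDR applied within steps 2 and 3
separately and additive (0/1/2) coding for local ancestry. Joint
variance attribution reports sequential $R^2$ in both orders, which
brackets each component's unique contribution; exact collinearity is
flagged rather than silently resolved.

# cis-eQTL mapping

Expression is inverse-normal transformed per gene, residualized on
covariates, and optionally on the leading principal components of the
covariate-residualized expression matrix. PCs stand in for Bayesian
latent-factor (PEER-style) estimates, whose point estimates they
approximate; for clean synthetic cohorts of a few hundred samples the
default is 0 factors, and a planted global batch shift is removed by a
single factor in the test suite.

The per-gene scan is simple linear regression of corrected expression
on each variant's dosage in the ±1 Mb window (MAF ≥ 0.01; zero-variance
dosages skipped). Gene-level calibration permutes expression across
samples, records each permutation's minimum nominal p, and fits a
Beta$(a, b)$ distribution to the minima by maximum likelihood
(method-of-moments start; ties jittered by machine epsilon; a
degenerate all-equal minima vector falls back to the empirical p with a
flag). The beta-approximated gene p is the fitted CDF at the observed
minimum. Permutation is adaptive: it stops once 30 permutation minima
beat the observed minimum (clearly non-significant genes), with a floor
of 100 and a default cap of 1000 permutations. Across genes,
Benjamini–Hochberg at FDR 0.05 defines eGenes; each significant gene's
nominal threshold inverts its fitted beta at the significance boundary
(midpoint between the largest significant and smallest non-significant
gene-level p — the GTEx convention). Significant variants are grouped
into independent signals by greedy LD clumping (take the best remaining
variant, absorb everything within 1 Mb with dosage $r^2 > 0.1$,
repeat).

# Fine-mapping and the anc-eQTL decision tree

Under a single-causal-variant assumption with a uniform prior over
variants, the posterior probability of variant $j$ is its Wakefield
approximate Bayes factor, normalized over the window:
$\mathrm{ABF}_j = \sqrt{\tfrac{se^2}{se^2 + W}}\,
\exp\!\big(\tfrac{z_j^2 W}{2(se^2 + W)}\big)$ with $se^2 \approx 1/n$
on the standardized scale and prior effect variance $W = 0.15^2$ by
default (configurable; the posterior ordering is insensitive to $W$,
and the level-0.95 credible-set coverage is verified empirically in the
acceptance suite). Credible sets take variants in decreasing posterior
order (ties broken by genomic position) until the cumulative posterior
reaches 0.95.

The cross-population configuration posterior assumes at most one causal
variant per group and enumerates the $(M+1)\times(M+1)$ grid of (causal
in high group, causal in low group) configurations, scored by products
of per-group ABFs under a uniform prior. Per variant it reports the
marginal probabilities of being causal in the high group only
(PP$_\mathrm{high}$), the low group only (PP$_\mathrm{low}$), or both
(PP$_\mathrm{shared}$); with the variant's null status these sum to 1.
Under the uniform prior the posterior factorizes across groups, making
the computation exact and fast. This replaces a genome-wide MCMC prior
estimation with fixed per-gene priors — a deliberate simplification:
the classifier consumes only the PP ordering and the 0.8 threshold.
Before this step, variant pairs with $r^2 > 0.95$ in *both* groups are
pruned to one representative (the smaller high-group p).

Effect-size heterogeneity between groups uses Cochran's Q on the two
marginal estimates, $Q = (\beta_h - \beta_l)^2/(se_h^2 + se_l^2)$
against $\chi^2_1$, Bonferroni-corrected by the number of genes
reaching the heterogeneity step. Because each group's expression is
inverse-normalized within group, the two estimates are on a common
scale; marginal-effect comparisons remain confounded by sampling error,
which is why the Bonferroni threshold is strict and the classifier
requires *every* credible-set variant to be heterogeneous.

The decision tree for each eligible gene (heritable eGene in the
high-ancestry group, i.e. h² LRT p < 0.05 and gene-level FDR < 0.05):

1. compare 95% credible sets between the high and low groups. A gene
   whose low group shows no mappable signal (not an eGene there) has no
   low-group credible set; the comparison is treated as nonoverlapping
   and flagged `low_group_silent`. A diffuse credible set computed from
   a null scan would cover most of the window and force spurious
   overlap, which is why the eGene gate is the default (`low_rule`).
2. nonoverlapping sets: **tier1** if a credible-set variant is common
   (MAF ≥ 0.01) in the high group and rare (< 0.01) or monomorphic in
   the low group. The default scope is *any* credible-set member — a
   gene holds a tier-1 call if it contains at least one such eQTL —
   because LD tags that are common in both groups frequently out-rank a
   genuinely private causal variant as the single lead; lead-only and
   all-member modes are available (`tier1_mode`).
3. otherwise **tier2** if all credible-set variants have
   PP$_\mathrm{high}$ > PP$_\mathrm{low}$ and PP$_\mathrm{high}$ >
   PP$_\mathrm{shared}$, with max PP$_\mathrm{high}$ > 0.8.
4. overlapping sets: **tier3** if every credible-set variant's Q
   p-value clears the Bonferroni threshold, else **shared**.
5. anything else: **none**.

Tier-2 and tier-3 recall on planted scenarios is deliberately modest:
the single-causal configuration posterior splits mass across strong
tags, and the all-members Bonferroni rule for tier 3 is conservative —
both mirror the rarity of these classes in real cohorts, and neither is
part of the package's calibration guarantees.

# TWAS

Per-gene elastic-net models (mixing 0.5, the PredictDB convention) are
trained with nested cross-validation: 10 outer folds give an honest
mean predicted–observed correlation (`rho_avg`) and its one-sided fold
z-test p (`zscore_pval`); 5 inner folds pick the penalty. The exact
outer/inner fold counts are conventions, recorded in the model objects.
Models pass the standard filters when `rho_avg` > 0.1, `zscore_pval` <
0.05 and the gene's heritability LRT p < 0.05. An optional mode
residualizes local-ancestry counts out of expression before training
(sensitivity analysis). Summary-statistic associations use
$z_g = \sum_l w_l\,(\sigma_l/\sigma_g)\, z_l$ with
$\sigma_g^2 = w^\top \Gamma w$ from an LD reference panel, after
aligning summary-statistic alleles to the model (sign flips on
swapped alleles; other mismatches dropped). When the LD reference
equals the GWAS population this is algebraically equivalent to
regressing the trait on predicted expression, which the acceptance
suite verifies.

# Benchmark problem sizes

The standing benchmark conditions, chosen once as desk-scale versions
of a realistic study and used by the acceptance suite and
`scripts/acceptance.R`:

* credible-set coverage: 500 cis-regions, 200 variants each, block LD
  $\rho = 0.6$, $n = 600$, causal variance 5–10%;
* heritability recovery: 200 genes at $h^2 = 0.3$, $n = 600$, with a
  Haseman–Elston regression oracle;
* directional group contrasts: 200 genes (70% shared / 30% private
  causal architecture), $h^2 = 0.15$, groups of 300, plus a balanced-
  admixture cohort of 800 for local-ancestry stratification;
* classifier benchmark: 100 genes per scenario, groups of 300,
  $h^2 = 0.1$, 60 variants per region;
* Cochran's Q calibration: 10,000 null effect pairs;
* permutation calibration: 50 genes spanning gene-level p from ~1 to
  below $10^{-3}$, against a 10,000-permutation empirical oracle;
* TWAS: 100 genes at $h^2 = 0.25$, training $n = 400$, GWAS $n = 2000$,
  10 additional null traits for z calibration;
* eGene FDR: 500 genes under a global null.

# Known limitations

* Single-causal fine-mapping understates the number of anc-eQTLs for
  genes with multiple independent signals, by design.
* The configuration posterior's uniform prior and
  single-causal-per-group assumption make tier-2 calls conservative in
  strong-LD regions.
* Unconstrained REML estimates for individual genes are noisy at a few
  hundred samples; the package's claims are about medians and means
  over many genes.
* The generator's LD is block-equicorrelated; methods whose behavior
  depends on long-range LD decay (e.g. clump counts per gene) are
  exercised only qualitatively.
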