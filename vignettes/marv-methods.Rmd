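---
title: "Multi-phenotype rare-variant burden testing by reverse regression"
author: "marv package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-phenotype rare-variant burden testing by reverse regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(marv)
```

## The problem

Single-variant association tests have essentially no power for rare
variants (RVs; here, minor allele frequency below 5%, covering both
"low-frequency" and "rare" in the usual nomenclature): too few carriers
exist for any one site. Burden tests recover power by collapsing all RVs
in a genomic region — a gene, an enhancer set, any user-defined interval —
into one per-individual score before regression. Independently, jointly
analysing several correlated phenotypes ("multi-phenotype analysis")
improves power over testing each phenotype separately, both by exploiting
the phenotypic correlation structure and by avoiding a multiple-testing
penalty. This package combines the two ideas.

## The model

For individual $i$, let $r_i$ be the number of region RVs at which $i$
carries at least one minor allele and $n_i$ the number of RVs successfully
typed for $i$. The burden proportion is $p_i = r_i / n_i$. For hard
genotype calls each variant contributes the 0/1 carrier indicator; for
imputed data it contributes the posterior probability of being
heterozygous or minor-homozygous, so $r_i$ is an expected carrier count.
Which allele is "minor" is always decided from the analysed sample's
computed allele frequency, never from REF/ALT labels, because the method
is defined on minor alleles and REF can be the minor allele.

The burden proportion is then modelled as a linear function of the $K$
phenotypes — *reverse* regression, with the genotype summary as outcome
and the phenotypes $\mathbf{y}_i$ as predictors:

$$ p_i = \alpha + \mathbf{y}_i^\top \boldsymbol\beta + \varepsilon_i, $$

fitted by weighted least squares with weights
$w_i = n_i / M$, the proportion of the region's $M$ RVs successfully
typed for $i$. Association is tested by a likelihood-ratio statistic
against the null $\boldsymbol\beta = 0$,

$$ \Lambda = 2(\ell_1 - \ell_0) = N \ln\frac{RSS_0}{RSS_1}, $$

referred to a $\chi^2_K$ distribution. Because phenotypes enter as
predictors, binary and continuous traits mix freely, and a region-level
test over $K$ phenotypes costs a single model fit.

For any region of interest every non-empty phenotype combination can be
refitted, each with its own LRT p-value and
$\mathrm{BIC} = -2\ln L + K\ln N$; the minimum-BIC combination is
reported as the best-fitting phenotype subset, which dissects *which*
traits drive a signal that the full model discovered.

## Numerical and definitional choices

Several details are deliberate choices of this implementation; they are
spelled out here because they affect reported numbers (never model
rankings or p-values).

* **Burden denominator versus weight.** With missing genotypes there are
  two natural denominators for the burden. We divide the carrier count by
  the *individual's observed* RV count, so $p_i$ is unbiased for the
  individual's carrier rate, and let the analysis weight
  $w_i = n_{\mathrm{obs},i}/M$ carry the completeness penalty — data
  quality enters the likelihood exactly once. With complete data the two
  conventions coincide ($w_i = 1$, $p_i$ the plain carrier fraction).
* **Likelihood normalisation.** The weighted Gaussian log-likelihood is
  evaluated as $\ell = -\tfrac{N}{2}[\ln(2\pi\hat\sigma^2) + 1] +
  \tfrac12\sum_i \ln w_i$ with $\hat\sigma^2 = RSS_w/N$. The
  $\sum \ln w_i$ term is identical for every phenotype subset fitted on
  the same individuals, so it cancels from every LRT statistic and every
  BIC difference; any other self-consistent constant would give identical
  inference. Absolute BIC values are therefore comparable only within a
  run.
* **BIC parameter count.** $K_{\mathrm{BIC}} = |S| + 2$ for subset $S$
  (slopes, intercept, residual variance). Only differences across subsets
  matter for selection, so any convention that adds a constant per model
  ranks subsets identically.
* **Complete-case set.** Individuals missing any full-model phenotype are
  dropped once and *all* subsets are refitted on that same set: BIC
  comparisons require a common $N$.
* **LRT from the RSS ratio.** $\Lambda$ is computed as
  $N\ln(RSS_0/RSS_1)$ rather than by subtracting log-likelihoods —
  algebraically identical under the normalisation above, numerically
  more robust when $RSS$ is tiny.
* **Ties and floors.** Best-subset ties break toward lower BIC, then
  fewer phenotypes, then enumeration order (subsets are enumerated by
  size, lexicographically within size, so univariate models come first).
  P-values below $10^{-300}$ are reported at that floor and flagged, to
  keep text output portable.
* **Filters.** Default variant filters are MAF < 5% and imputation
  info ≥ 0.4; variants without an info score (directly genotyped ones)
  pass the info filter. Multi-allelic VCF sites are decomposed per
  alternate allele, each filtered and collapsed independently;
  half-missing genotype calls are treated as missing. IMPUTE2 GEN
  probability triplets whose mass deviates from 1 by more than 0.02 are
  set missing with a warning.
* **Degenerate regions.** A region whose burden proportion is constant
  on the analysis set (e.g. no carriers) cannot be tested; it is skipped
  with an explicit reason rather than returning a spurious p-value.

Phenotypes are typically pre-adjusted before testing:
`adjust_covariates()` residualises a trait on covariates (sex, BMI,
genetic principal components, ...) and `inverse_normal_transform()` maps
the residuals onto standard-normal quantiles using Blom rank scores
($c = 3/8$). Covariates are handled by this pre-adjustment rather than
inside the reverse regression, keeping the genotype-side model minimal.

## The synthetic-data generator

Operating characteristics are estimated on synthetic data whose
statistical structure mirrors a realistic rare-variant study:

* **Locus.** `build_locus()` records the "average gene" layout used to
  frame the simulations — 8 exons × 300 bp alternating with 7 introns ×
  3 kb (coding 2.4 kb, transcript 23.4 kb) plus 100 kb flanks.
* **Frequency spectrum.** Forward demographic simulation of such a locus
  (ancestral size 8100, bottleneck to 2000, then 1.29% exponential growth
  over 370 generations, mutation rate $2\times10^{-8}$/bp/generation)
  produces an allele-frequency spectrum in which roughly 96% of variants
  have MAF < 5%. Running such a simulation is far outside desk scale, and
  the burden test's behaviour depends on the spectrum and the causal
  structure, not on haplotype history — so `sample_maf_spectrum()`
  emulates the spectrum parametrically: MAFs are drawn from a Beta
  distribution truncated to $(0, 0.5]$ with first shape 0.1 (the near
  $1/x$ shape of a neutral site-frequency spectrum) and second shape
  solved numerically so the expected rare fraction hits the 0.96 target.
  A consequence worth stating plainly: simulated variants are in linkage
  equilibrium. Real RVs carry (weak) LD, which the generator does not
  reproduce, so passing simulations demonstrate calibration and relative
  power under independence, not robustness to haplotype structure.
* **Genotypes.** Hardy–Weinberg sampling, allele counts
  $\sim\text{Binomial}(2, \text{MAF})$, independently per variant;
  per replicate the genotypes are regenerated from the fixed MAF vector
  rather than subsampled from a stored mega-population (equivalent at the
  level of HWE marginals, and it removes any need for a 500 000-individual
  pool).
* **Causal variants.** Drawn at random among variants with MAF < 2%,
  accumulating while the selected MAFs sum to at most 5% — rare causal
  variants of modest aggregate frequency. The causal set is frozen per
  scenario and shared by all its replicates.
* **Phenotypes.** Two continuous traits
  $y_j = \sum_k \beta_{kj} g_k + \epsilon_j$ with
  $(\epsilon_1,\epsilon_2) \sim \mathrm{MVN}(0, \Sigma)$, unit variances
  and correlation $\rho \in [-0.9, 0.9]$. Effect magnitude defaults to
  $\beta = 0.1$ per minor allele; patterns (a)–(d) set the second trait's
  effects to $+\beta$, $-\beta$, $\beta/2$ or $0$, and the direction mix
  optionally makes every second causal variant trait-decreasing.
* **Region size.** The default simulated region holds 150 rare variants
  — the same order as the causal-set sizes that the MAF-sum rule produces
  on realistic spectra — with the causal subset selected on top. Binary
  phenotype simulation is not provided (continuous traits are the case of
  interest for calibration; binary traits enter the test itself without
  any special handling).

All randomness flows from one scenario seed through derived sub-streams
(spectrum, causal draw, per-replicate), so any single replicate can be
regenerated in isolation and file fixtures are bit-reproducible.

## Evaluation harness

`rejection_rate()` pushes every replicate through the *full* analysis
path — sample-MAF rare-variant filter, carrier collapse, weighted
regression — and reports the fraction of replicates with $p$ below the
nominal level, with a Clopper–Pearson 95% interval. Under a null
scenario that fraction estimates the type-I error; under an effect
scenario, power. The univariate comparator regresses each phenotype on
the burden (forward direction, same weights) and counts a replicate as
detected when its smaller p-value clears the Bonferroni-split level
$\alpha/2$; with unit weights and one phenotype the forward and reverse
tests are numerically identical, which the test suite asserts.
`power_grid()` evaluates all methods on *shared* replicates so power
differences are paired comparisons, and per-replicate p-values can be
kept so other $\alpha$ levels need no re-simulation. Replicates whose
region degenerates (no polymorphic rare variant) are excluded and
counted; a custom test plugs in as a function `(burden, phenotypes) -> p`.

Problem sizes in the shipped tests were chosen to make Monte-Carlo error
small relative to the effects being asserted while staying comfortably
desk-scale: calibration checks use 2000 replicates at $N = 1000$, and the
power-pattern checks use 1000 replicates per cell at $N = 5000$ on the
correlation grid $\{-0.9, 0, 0.9\}$. The expected qualitative patterns —
negative correlation boosting power for same-direction effects, positive
for opposing effects, either extreme for single-trait effects, and the
joint test dominating the Bonferroni-corrected univariate analysis — are
asserted as paired comparisons rather than against fixed power numbers,
since absolute power depends on the realised causal set.

## Known limitations

* Burden collapsing assumes a large fraction of causal RVs with aligned
  effects; with mixed effect directions power drops (the half-and-half
  direction mix exhibits this), and variance-component or combined tests
  are more robust in that regime.
* No LD, no haplotype structure, no annotation-informed variant masks in
  the generator (user-supplied include/exclude lists aside).
* Covariates must be handled by phenotype pre-adjustment; relatedness is
  not modelled.
* Absolute BIC values depend on the likelihood normalisation; compare
  them only within a run.
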