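---
title: "Stability-guided fine-mapping: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stability-guided fine-mapping: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stabfm)
```

## The problem

Genetic fine-mapping asks which variant(s) in an associated locus causally
affect a trait, given that linkage disequilibrium (LD) makes dozens of
variants nearly interchangeable statistically. Standard practice adjusts for
population structure by residualizing the trait on top genotype principal
components before fine-mapping. Residualization, however, may not remove all
confounding, particularly in multi-ancestry cohorts where subpopulations
differ in both LD patterns and environmental exposures. This package
implements a complementary idea: a causal variant should act through the same
mechanism in every subpopulation, so a fine-mapper re-run on each
ancestry-defined slice of the cohort should keep reporting it. Variants that
are consistently supported across slices are called *stable*; variants found
after residualization are called *top* variants.

## The permutation fine-mapper

`pics()` is a non-parametric, Bayesian fine-mapper. For a locus with dosage
matrix $X$ ($N$ samples by $P$ variants) and trait $y$, the marginal
association of each variant is its squared Pearson correlation with $y$
(`marginal_assoc()`); the *lead SNP* $\ell$ is the argmax. For the posterior
probability that a focal variant $j$ is causal given that $\ell$ leads, Bayes'
theorem factorizes the posterior into (i) the probability that $\ell$ emerges
as lead were $j$ causal, times (ii) $j$'s prior. Term (i) is estimated by
permutation: rows of $X$ are shuffled only *within strata defined by the focal
variant's dosage value*. This family of permutations is the unique
row-permutation group that leaves the focal variant's association with the
trait exactly invariant while preserving every pairwise column correlation
(rows move as whole units), so it perturbs the data without destroying either
the focal signal or the LD fabric. Across `R` such permutations we count how
often $\ell$ remains the strongest association within its LD neighbourhood
$\{k : \mathrm{cor}(A_k, A_\ell)^2 > r^2\}$; the counts, multiplied by the
prior and normalized, form the posterior vector of one *potential set*. The
neighbourhood's columns are then removed and the procedure repeats, giving up
to `C` disjoint potential sets ranked from strongest to weakest marginal
signal.

Two implementation notes. First, because the within-stratum permutation group
is closed under inversion, permuting $y$ by a group element gives the same
null distribution as permuting the rows of $X$; the implementation exploits
this to turn the inner loop into one matrix cross-product per focal variant.
The exported `constrained_permutation()` still returns genuine row
permutations, and the test suite verifies exact invariance of the focal
column, the row multiset, and all pairwise correlations, plus agreement of
Monte-Carlo posteriors with exhaustive enumeration of the group on small
loci. Second, the exact mathematical definition of the "valid" permutation
family is our reconstruction from the two invariance requirements; it is the
only family satisfying both, but readers comparing against other
implementations should be aware the choice is made explicit here.

### Parameters

| Parameter | Default | Meaning |
|---|---|---|
| `r_threshold` | 0.5 | LD magnitude defining a lead's neighbourhood (dimensionless correlation) |
| `R` | 500 | permutations per focal SNP |
| `C` | 3 | potential sets returned (strong/moderate/weak association) |
| `prior` | uniform $1/P$ | prior causal weights; rescaling by a positive constant provably does not change the posterior |
| `seed` | none | one RNG is seeded per `pics()` call; permutations for successive focal SNPs are drawn sequentially from it, so results are reproducible given the seed and the documented iteration order |

Ties in any argmax (lead selection, permuted lead checks, final variant
selection) are broken by smallest genomic position, then lexicographically
smallest variant id — determinism matters because the procedure is permutation
based and downstream agreement statistics compare variant identities.

## The four selection strategies

* **plain** (`plain_select`): pooled-sample argmax per potential set; no
  structure correction of any kind.
* **top** (`top_select`): the phenotype is residualized on the top `n_pcs`
  (default 5, chosen by the conventional eigenvalue elbow; an automated elbow
  utility `elbow_n_pcs()` is provided but is deliberately not the default)
  genotype principal components — PCA on centered, unscaled dosages — and the
  backend is run on the residuals.
* **stable** (`stable_select`): the backend runs once on the pooled,
  unresidualized data and once per subpopulation slice. For potential set
  $c$, candidate variants are those with positive probability in the pooled
  vector; among them, keep the ones positive in the greatest number of
  probability vectors (pooled + available slices), and report the one with
  the largest pooled probability. Slices with fewer than 3 samples are
  skipped (correlations degenerate); a slice that produced fewer than $c$
  sets simply contributes no vector for set $c$.
* **combined** (`combined_select`): the stability rule applied to the
  residualized phenotype.

Slice runs recompute their own lead SNPs and neighbourhoods — each slice run
is a full, independent invocation of the fine-mapper on that slice's data,
not a re-scoring of the pooled sets. This is the natural reading of "run the
algorithm on each slice" and is what makes the stability perturbation a real
perturbation.

The stability wrapper is backend-agnostic. A backend is any function
`(genotypes, phenotype, params) -> list of posterior vectors` carrying a
`support_rule` attribute saying which entries count as "positive".
`backend_pics()` uses strict positivity. `backend_susie()` wraps a minimal
iterative Bayesian single-effect fine-mapper whose per-effect probability
vectors are dense, so its rule is PIP $\ge 1/(\text{variants included})$
(`susie_support_filter()`), the prior inclusion probability. This built-in
single-effect backend exists to exercise the contract with PIP-style
vectors; it is not a port of the reference variational SuSiE algorithm and
makes no claim of numerical parity with it. For PIP-style backends the
"pooled probability" used in the final argmax is the PIP itself; we flag this
as a convention rather than a derivation.

## The phenotype simulator

`simulate_phenotype()` generates cis-eQTL-like traits over any genotype
matrix: `n_causal` variant indices are drawn uniformly (restricted to
variants with minor allele frequency at least `min_maf`, default 0.01, to
avoid degenerate monomorphic picks), effects are
$b_j \sim N(0, \texttt{effect\_sd}^2)$ with `effect_sd` = 0.6, the exogenous
variance is set to $\sigma^2 = \mathrm{var}(Xb)(1-\phi)/\phi$ so the
proportion of variance explained is $\phi$ — equivalently the signal-to-noise
ratio is $\phi/(1-\phi)$, about 0.67 at $\phi = 0.4$ and 0.053 at
$\phi = 0.05$ — and $y = Xb + \varepsilon$. `var()` here is the empirical
$N-1$ variance of the realized genetic values, matching the "proportion of
variance in $y$ explained" reading of $\phi$.

Environmental heterogeneity by ancestry comes in two flavours, over the five
cohort subpopulations in the fixed order (TSI, GBR, FIN, CEU, YRI) with sizes
(91, 86, 92, 89, 87):

* *Variance heterogeneity* (`"t=8"`, `"t=16"`, `"t=128"`, `"t=256"`): noise
  variances become $5\sigma^2 \alpha(t)$ where
  $\alpha_{POP}(t) = N_{POP}^t / \sum N^t$ are exponentiated population-size
  proportions, computed in log space so that $t = 256$ does not overflow.
  $t = 0$ reproduces the homogeneous model *exactly* (equal variances), which
  the tests assert as an identity, not a tolerance.
* *Mean heterogeneity*: noise means shift by population,
  $\mu = (2\sigma, 0, \sigma, \sigma, 2\sigma)$ for the smooth shift and
  $\mu = (0, 2\sigma, 0, 0, 0)$ for the spiked shift that singles out GBR;
  $\sigma$ is the square root of the baseline $\sigma^2$.

Noise is independent across individuals in every scenario.

`simulation_grid()` enumerates the factorial design (loci x causal counts x
$\phi$ x replicates x scenarios) deterministically; each cell's seed is a
32-bit hash of its coordinates and the master seed, so grids are reproducible
and fresh effects are drawn per replicate (the alternative — reusing effects
across replicates — halves the effective design, and nothing in the model
requires it).

## The synthetic genotype generator

`synth_genotypes()` stands in for real reference-panel genotypes. Each
haplotype is a latent AR(1) Gaussian chain (lag-1 correlation `ld_rho`,
restarting at block boundaries every `ld_block_size` variants) thresholded at
frequency-matched quantiles, so marginal allele frequencies are exact and
within-block LD is controllable; per-population frequencies drift from shared
ancestral frequencies by a Balding–Nichols beta perturbation with parameter
`fst_like_drift`. Defaults: 100 variants in blocks of 10, `ld_rho = 0.9`
(thresholding attenuates latent correlation, so this yields adjacent *dosage*
correlations around 0.5–0.6, i.e. haplotype-block-like neighbourhoods of a
few variants around each lead), ancestral MAF uniform on (0.05, 0.5), drift
0.02 (allele-frequency differentiation of a few percent, in the range of
European–European pairs and below European–African pairs).

What the generator does *not* emulate: recombination-rate variation and
long-range LD, allele-frequency spectra skewed toward rare variants,
cryptic relatedness, genotyping error, and any real environmental
correlates of ancestry beyond the simulator's explicit noise scenarios.
Passing tests on this generator therefore demonstrate correctness and
internal calibration of the algorithms, and directional behaviour of the
comparison statistics — not the full-scale empirical effect sizes obtainable only
with real reference genotypes and expression data.

## Evaluation and annotation comparisons

`evaluate_selection()` records, per dataset/method/potential set, both
"recovered" senses: the selected variant is causal, and the set's support
contains at least one causal variant; tables label which flag they average.
`recovery()` reports stratified frequencies with Wald 95% intervals
($\pm 1.96$ standard errors, truncated to $[0,1]$). `mcnemar()` uses the
exact binomial form on discordant pairs — at the problem sizes for which this
package is intended the discordant counts are small, where the chi-square
approximation is poorest. `matching()` and `matching_enrichment()` quantify
between-method agreement and the causal-recovery advantage of agreeing
selections.

For annotation work, `wilcoxon_compare()` runs one-sided rank tests (unpaired
for matching vs non-matching variants, signed-rank for paired top-vs-stable
deltas; exact p-values up to n = 50, normal approximation with continuity
correction beyond), with Benjamini–Hochberg adjustment applied jointly across
annotations within a comparison family. `moderators()` computes the six
moderator variables of the trend analysis; pairwise allele-frequency
differences use ALT-allele frequencies (absolute differences make the
ALT/minor choice immaterial in practice), and pairwise $F_{ST}$ uses Hudson's
two-population form $(p_1 - p_2)^2 / (p_1(1-p_2) + p_2(1-p_1))$ — chosen over
the sample-size-corrected variant so that identical frequencies give exactly
zero and fixed alternative alleles give exactly one, the two boundary
behaviours the rest of the package relies on; the Weir–Cockerham estimator
is available via `estimator = "wc"`. `trend_tests()` routes each moderator to
its test: a permutation Jonckheere–Terpstra test (5000 permutations by
default) for the ordinal degree of stability, Pearson correlation tests for
continuous moderators, unpaired Wilcoxon for the binary Yoruban-support
flags; BH is applied within moderator.

## Numerical and degenerate-input conventions

* Posterior vectors must sum to 1 within 1e-9; round-trips through TSV
  preserve probabilities to better than 1e-12.
* Monomorphic variants get association 0 and are never leads while any
  polymorphic variant remains; a fully monomorphic locus is an error.
* Constant phenotypes, empty cis windows, and empty loci raise errors rather
  than propagating NaNs.
* Missing genotypes are imputed to the rounded per-variant mean at read time
  (the permutation machinery moves whole rows, so NA propagation would
  corrupt strata); the imputation count is reported. How the original
  analyses handled missing reference-panel genotypes is not documented, so
  mean imputation is this package's choice.
* Multiallelic VCF records keep the first ALT allele with a warning; dosages
  only, no strand/allele flipping.
* If a lead never emerges in any permutation for any focal variant (possible
  at tiny R), the posterior falls back to the prior over the neighbourhood
  with a warning rather than dividing by zero.

## Problem sizes used by the test suite

The tests and the worked examples run at deliberately modest scale, chosen as
the smallest sizes at which each property is statistically identifiable: the
cohort layout (445 samples in five subpopulations) matches the study design
the simulator emulates; loci of 80–100 variants in blocks of 10; `R` between
60 and 100 for end-to-end runs, 10,000 where Monte-Carlo/exhaustive agreement
is asserted; a 20-locus, two-$\phi$, two-causal-count grid for the
directional recovery and enrichment checks. Paper-scale grids (hundreds of
loci, `R = 500`) use the same code paths via `run_pipeline()` and
`simulation_grid()`.

## Known limitations

* The stability rule assumes at most one prioritized variant per potential
  set; co-causal variants inside one LD neighbourhood are not separated.
* PICS probabilities are not posterior inclusion probabilities in the strict
  linear-model sense, so credible-set coverage metrics are intentionally not
  offered.
* The built-in single-effect backend is a testing aid; for production
  SuSiE-style analyses, wrap the reference implementation with
  `backend_susie()`'s contract (a list of per-effect probability vectors plus
  the PIP support rule).
* Paper-scale empirical findings (headline recovery rates, agreement
  percentages, enrichment folds on real cohorts) require real genotype and
  expression data; this package reproduces their *directional* counterparts
  on synthetic data and provides the machinery to rerun the real analyses
  when those data are available.
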