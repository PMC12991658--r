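# stabfm — stability-guided genetic fine-mapping

Fine-mapping asks which variant in an associated locus actually drives a
trait, when linkage disequilibrium (LD) makes neighbouring variants almost
statistically interchangeable. The usual guard against population-structure
confounding is residualization: regress the top genotype principal components
out of the trait before fine-mapping. `stabfm` implements a complementary,
non-parametric strategy built on *stability*: a truly causal variant should
keep being reported when the fine-mapper is re-run separately on each
ancestry-defined slice of the cohort. The package is aimed at statistical
geneticists analysing multi-ancestry eQTL or GWAS cohorts, and at
methodologists studying when residualization and stability guidance agree.

## What it computes

**Permutation fine-mapper (`pics()`).** For dosage matrix **X** (N×P) and
trait **y**, the lead SNP ℓ maximizes the marginal r². For each focal SNP j
in the lead's LD neighbourhood 𝒩ℓ = {k : cor(A_k, A_ℓ)² > r²} (default
|r| = 0.5), the posterior that j is causal follows Bayes' theorem,

&nbsp;&nbsp;&nbsp;&nbsp;P(A_j causal | A_ℓ leads) ∝ P(A_ℓ leads | A_j causal) · P(A_j causal),

with the first factor estimated as the fraction of R (default 500)
*constrained permutations* — row shuffles within the strata of j's dosage
values, which exactly preserve j's association with y and every pairwise LD
correlation — in which ℓ re-emerges as the neighbourhood's strongest
association. Normalized over 𝒩ℓ these form one *potential set*; the
neighbourhood is removed and the loop repeats up to C (default 3) times.

**Selection strategies.** `plain_select()` takes the pooled argmax.
`top_select()` fine-maps the phenotype residualized on the top 5 genotype
PCs (the *top variant*). `stable_select()` re-runs the fine-mapper on the
pooled sample and on each subpopulation slice, keeps the pooled-supported
variants that are positive in the most probability vectors, and reports the
one with the largest pooled probability (the *stable variant*).
`combined_select()` applies the stability rule to the residualized trait.
Any backend honouring the posterior-vector contract plugs into the wrapper,
including PIP-style fine-mappers via the 1/(variants included) support rule.

**Simulator, evaluation, annotation statistics.** A cis-eQTL phenotype
simulator (y ~ N(Xb, σ²I) with σ² solved from the target proportion of
variance explained φ, so SNR = φ/(1−φ); variance- and mean-heterogeneity
scenarios by ancestry), synthetic block-LD genotypes for five labelled
subpopulations, recovery frequencies with 95% CIs, exact McNemar paired
comparisons, matching-enrichment statistics, one-sided Wilcoxon annotation
comparisons with Benjamini–Hochberg correction, the six stability
moderators (including Hudson F_ST), and permutation Jonckheere–Terpstra
trend tests.

## Worked example

```r
library(stabfm)

g   <- synth_genotypes(n_variants = 80, seed = 7)        # 445 samples, 5 populations
sim <- simulate_phenotype(g, simulation_spec(n_causal = 2, phi = 0.4, seed = 7))
g$variant_ids[sim$causal]
#> [1] "A31" "A42"

params <- pics_params(R = 200, seed = 7)
pics(g, sim$values, params)
#> pics fit: 3 potential set(s), 445 samples, 80 variants
#>   Potential Set 1: lead A31, 2 variants in support, max prob 1.000 (A31)
#>   Potential Set 2: lead A34, 2 variants in support, max prob 1.000 (A34)
#>   Potential Set 3: lead A42, 3 variants in support, max prob 0.725 (A42)

stable_select(g, sim$values, params = params)
#> finemap_selection (stable): 3 potential set(s)
#>  potential_set variant_id variant_index pooled_prob support_count in_yri_support method
#>              1        A31            31   1.0000000             6           TRUE stable
#>              2        A34            34   1.0000000             4          FALSE stable
#>              3        A42            42   0.7246377             1          FALSE stable
```

Both simulated causal variants are recovered: A31 tops Potential Set 1 with
pooled posterior 1.0 and positive probability in all six probability vectors
(pooled + five slices, `support_count = 6`), including the Yoruban slice;
A42, the weaker signal, surfaces in Potential Set 3. `top_select()` on the
same data picks A31 for Set 1 as well — an agreeing ("matching") selection,
which in simulations is substantially more likely to be causal than
selections on which the two approaches disagree.

The textbook stability rule on plain probability vectors:

```r
pooled <- list(c(0.45, 0.43, 0.02, 0.10, 0.00))
s1     <- list(c(0.00, 0.40, 0.10, 0.25, 0.25))
s2     <- list(c(0.20, 0.60, 0.00, 0.10, 0.10))
# variants 2 and 4 are positive in all three vectors; variant 2 has the
# larger pooled probability, so the stable variant is A2 at 0.43
```

An end-to-end experiment (simulate → fine-map with every mode → evaluate):

```r
res <- run_pipeline(list(seed = 1, simulation = list(n_loci = 5)))
res$recovery_table     # recovery by method, potential set, phi, with 95% CIs
res$matching_table     # top/stable agreement per potential set
```

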