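# gsfactors

Benchmarking the factors that drive genomic prediction accuracy.

Genomic selection ranks breeding candidates on genome-wide
marker-predicted genetic merit, and how well that works depends on more
than the statistical method: marker density, minor allele frequency
spectrum, trait heritability and genetic architecture all move the
cross-validated accuracy, sometimes in opposite directions for different
methods. `gsfactors` packages the models and the experimental harness
needed to study those factors side by side, for breeders and quantitative
geneticists who want controlled, reproducible comparisons rather than
one-off scripts.

## What is implemented

**Models.** Additive GBLUP (`gblup_a`) and additive-plus-dominance GBLUP
(`gblup_ad`) fitted by average-information REML with EM fallback, using
the VanRaden additive relationship matrix

    G_a = W_a W_a' / (2 Σ_j p_j (1 − p_j)),   W_a coding: 2−2p (AA), 1−2p (AB), −2p (BB)

and the Aliloo dominance matrix

    G_d = W_d W_d' / (4 Σ_j (p_j(1−p_j))²),   W_d coding: −2(1−p)² (AA), 2p(1−p) (AB), −2p² (BB).

BayesR (`bayesr`): whole-genome regression with SNP effects from the
four-component normal mixture

    g_j ~ π₁ N(0, 0) + π₂ N(0, 10⁻⁴ σ²_g) + π₃ N(0, 10⁻³ σ²_g) + π₄ N(0, 10⁻² σ²_g)

sampled by a compiled single-site Gibbs sampler (50,000 iterations /
20,000 burn-in by default) with Geweke convergence diagnostics.

**Harness.** Replicated k-fold cross-validation (5 folds × 10 replicates
by default) with pooled held-out Pearson accuracy; nested marker-density
subsampling (low-density panels are subsets of high-density ones);
MAF-threshold experiments with size-matched random control panels;
MCMC iteration-budget experiments; heritability summaries across
replicates.

**IO and QC.** VCF (GT field, biallelic), PLINK .bed/.bim/.fam, and plain
dosage TSV readers; phenotype TSV; MAF, call-rate and Hardy-Weinberg
filters with logged removal counts; mean imputation; GRM TSV
serialization.

**Simulator.** Genotypes from a one-parameter LD chain with controllable
minor-allele-frequency range, plus traits of controllable heritability
and architecture: single QTN, BayesR-class normal mixtures, dominance,
and liability-threshold case-control.

## A worked example

Simulate a cohort with moderate LD, give it a polygenic trait at
heritability 0.5, estimate variance components, and measure replicated
cross-validated accuracy for GBLUP-A:

```r
library(gsfactors)

g  <- simulate_genotypes(genotype_sim_config(n = 500, m = 1000,
                                             ld_rho = 0.5, seed = 11))
tr <- simulate_trait(g, trait_architecture("mixture", h2_target = 0.5),
                     seed = 3)
tr
#> simulated_trait (mixture): n=500, 57 causal markers, realized h2 = 0.500 (target 0.500)

vc <- reml_fit(tr$phenotype, make_grm(g, "additive"))
vc
#> variance_components (ai-REML, 7 iterations, converged)
#> additive residual
#> 0.056313 0.051875
#> h2: additive=0.5205 total=0.5205

plan <- make_cv_plan(500, n_folds = 5, n_replicates = 10, root_seed = 7)
run_cv("gblup_a", g, tr$phenotype, plan)
#> accuracy_result [gblup_a, trait, m=1000]: mean r = 0.3933 (se 0.007705) over 10 replicates
```

The REML fit recovers the simulated heritability (ĥ² ≈ 0.52 for a true
0.5), and the cross-validated accuracy of about 0.39 sits well below
√0.5 ≈ 0.71: with only 500 samples and weak relatedness the breeding
values themselves are estimated with substantial error, so accuracy is
governed by the effective number of independent genome segments, not by
heritability alone. The same call with `"bayesr"` or `"gblup_ad"` swaps
the method under identical folds; `density_experiment()`,
`maf_experiment()` and `qtn_inclusion_experiment()` run the factor
studies and return long-format tables.

Config-driven runs (YAML in, TSV tables + manifest out) go through
`run_experiment()`; a thin CLI wrapper lives in `inst/scripts/gsfactors`.

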