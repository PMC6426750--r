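---
title: "Models and methods behind gsfactors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gsfactors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsfactors)
options(gsfactors.quiet = TRUE)
```

`gsfactors` is a benchmarking toolkit for genomic selection: it implements
additive GBLUP, additive-plus-dominance GBLUP, and the BayesR
normal-mixture regression, together with the replicated cross-validation
protocol and the marker-density, minor-allele-frequency and
genetic-architecture experiments used to compare them. This vignette is
the package's account of the underlying models, the choices the
implementation makes where a choice was open, and what the simulation
studies can and cannot show.

## Mixed models and genomic relationship matrices

The additive model is

$$ y = X b + Z_a u_a + e, \qquad
   u_a \sim \mathcal{N}(0, G_a \sigma^2_{u_a}), \quad
   e \sim \mathcal{N}(0, I \sigma^2_e), $$

with the VanRaden genomic relationship matrix
$G_a = W_a W_a' / \big(2 \sum_j p_j (1 - p_j)\big)$, where the incidence
codes are $2 - 2p_j$, $1 - 2p_j$ and $-2p_j$ for genotypes AA, AB and BB —
equivalently, allele-A dosage minus $2p_j$. The additive-dominance model
adds $Z_d u_d$ with $u_d \sim \mathcal{N}(0, G_d \sigma^2_{u_d})$ and the
Aliloo dominance matrix
$G_d = W_d W_d' / \big(4 \sum_j (p_j(1-p_j))^2\big)$, with codes
$-2(1-p_j)^2$, $2 p_j (1-p_j)$, $-2 p_j^2$. Both matrices are invariant to
swapping which allele is counted, which the test suite verifies. Under
Hardy–Weinberg genotype proportions the expected diagonal of $G_a$ is 1.

Allele frequencies entering $W$ and the scaling denominators are the
observed frequencies of the full post-QC panel and are *not* recomputed
per cross-validation fold or per marker-density subset: one relationship
matrix is built per marker set and sub-indexed per fold, which is valid
because its construction uses no phenotypes. `additive_incidence()` and
the GRM constructors accept explicit frequencies for callers who want a
different reference.

### REML

`reml_fit()` estimates variance components by average-information (AI)
REML. The first iteration, and any AI proposal that either leaves the
parameter space or would decrease the restricted likelihood, falls back to
an EM update, which cannot go negative and never decreases the restricted
likelihood (a property the tests assert). Convergence is declared when
successive restricted log-likelihoods change by less than $10^{-8}$;
components are constrained above $10^{-10}\,\mathrm{Var}(y)$ and reported
as exactly 0 when they finish at that pin, so a boundary fit (for example
a dominance variance of zero, or a residual variance of zero for a fully
heritable trait) prints the way variance-component tables conventionally
report it.

Two computational backends implement the same updates. With a single
genomic kernel the likelihood is evaluated in the eigenbasis of $G$, where
the covariance is diagonal and every iteration costs $O(nq)$ after one
eigendecomposition — this is what makes replicated five-fold
cross-validation with per-fold refitting affordable. With two kernels
(additive plus dominance) the dense-matrix form is used.

Predictions for unphenotyped individuals use the conditional-expectation
form on the full relationship matrix,
$\hat u = \sigma^2_u G[\cdot, t]\, V_{tt}^{-1} (y_t - X_t \hat b)$, which
is algebraically identical to solving the mixed-model equations with the
validation phenotypes set missing. GBLUP-A predictions are exactly the
marker-ridge-regression solution with penalty
$\lambda = \sigma^2_e \big/ \big(\sigma^2_{u_a} / 2\sum_j p_j(1-p_j)\big)$;
the acceptance suite checks this equivalence to machine tolerance, and it
is the reason a relationship-based and a marker-based view of GBLUP can be
used interchangeably.

For the additive-dominance fits the "total" heritability is defined as the
sum of the additive and dominance ratios from one joint fit. The model
reports `h2_additive`, `h2_dominance` and their sum; published tables
sometimes show a combined column fitted separately, which can differ
slightly from the sum — this package always reports the sum.

## BayesR

The marker-effect model keeps the printed four-component mixture prior

$$ g_j \sim \pi_1\,\mathcal{N}(0, 0) + \pi_2\,\mathcal{N}(0, 10^{-4}\sigma^2_g)
   + \pi_3\,\mathcal{N}(0, 10^{-3}\sigma^2_g) + \pi_4\,\mathcal{N}(0, 10^{-2}\sigma^2_g), $$

with the relative variance of each component fixed and
$\pi_1+\pi_2+\pi_3+\pi_4 = 1$. The Gibbs sampler (compiled C++, driven by
R's RNG so `set.seed()` governs it end to end) updates, per iteration:
fixed effects under a flat prior; each SNP by first drawing its component
indicator from the four-way conditional with the effect integrated out —
marginalizing is required for adequate mixing — and then, for a non-null
component, the effect from its conditional normal; $\pi$ from a
Dirichlet(1,1,1,1) posterior; $\sigma^2_g$ from its scaled inverse
chi-square conditional (prior degrees of freedom 4, scale set from
$0.5\,\mathrm{Var}(y)$); and $\sigma^2_e$ from a flat scaled inverse
chi-square ($\nu = -2$, $S = 0$). Defaults are 50,000 iterations with
20,000 burn-in; when only a total budget is given, burn-in is 40% of it.
No thinning: all post-burn-in draws enter the posterior means.

Implementation notes that matter numerically: dosage columns are centered
by $2p_j$ before sampling (the intercept absorbs the shift; the model is
unchanged, mixing improves); the residual vector is updated by single-site
downdates and recomputed in full every 1,000 iterations to cap
floating-point drift; `fix_pi`, `fix_sigma_g` and `fix_sigma_e` exist as
diagnostic modes, and the oracle test uses them to compare the sampler
with the conjugate closed form.

Convergence is monitored with Geweke z-scores (first 10% versus last 50%
of the post-burn-in chain, spectral variance from an AR fit) on
$\sigma^2_g$, $\sigma^2_e$ and each $\pi_k$; a chain is flagged converged
when all $|z| < 2$.

One caution on interpreting $\sigma^2_g$: with raw-dosage (centered, not
standardized) genotypes, $\sigma^2_g + \sigma^2_e \approx \mathrm{Var}(y)$
only when the causal configuration satisfies
$\sum_j \gamma_{k(j)} \mathrm{Var}(z_j) \approx 1$ — the self-consistent
case in which $\sigma^2_g$ carries its total-genetic-variance
interpretation. Away from that configuration, and in short chains,
$\sigma^2_g$ is only softly identified; the test suite checks the variance
decomposition under the self-consistent design, averaged over trait
replicates, and the Geweke diagnostic flags the short-chain regime.

## The evaluation protocol

`make_cv_plan()` builds replicated k-fold partitions (defaults: 5 folds,
10 replicates) from one root seed; every derived seed (per replicate, per
fold, per experiment stage) is a deterministic function of it via
`child_seed()`, and nothing in the package reads entropy outside the
configured seeds. Accuracy is the Pearson correlation between pooled
held-out predictions and observed phenotypes — one correlation per
replicate over all samples, rather than a mean of per-fold correlations,
which uses every sample exactly once per replicate and halves the
estimator variance. Variance components are re-estimated on every
training fold. Case-control traits are evaluated with the same Pearson
correlation on the 0/1 scale.

Marker-density experiments draw nested panels: one permutation per seed,
truncated at each requested size, so lower-density panels are subsets of
higher-density ones. MAF experiments pair each filtered panel with a
random control panel of exactly the same size drawn without MAF
restriction (when a threshold removes nothing, the control *is* the
filtered panel and its result is reused rather than recomputed).

Quality control follows the conventional inclusive-keep reading of
removal rules stated with strict inequalities: markers are kept when call
rate $\ge$ 0.95, MAF $\ge$ threshold, and Hardy–Weinberg p-value $\ge$
$10^{-4}$. The HWE test is the 1-df Pearson chi-square — adequate at chip
scale and the conventional meaning of an HWE p-value threshold — with
monomorphic markers assigned p-value 1 (and MAF 0, so any positive MAF
filter removes them). Missing calls are mean-imputed ($2p_j$) before any
matrix algebra; allele frequencies always come from observed calls only.
How chip data were imputed upstream is typically undocumented; mean
imputation is this package's choice.

## The simulator

`simulate_genotypes()` produces biallelic dosages from $2n$ haplotypes
generated as a first-order copying chain: the allele at marker $j$ copies
marker $j-1$ with probability `ld_rho`, else is drawn fresh at that
marker's frequency. This one-parameter model yields Hardy–Weinberg
proportions marginally, a controllable adjacent-marker correlation, and a
geometric decay of LD with distance — enough structure for the
marker–QTN-tagging gradients the experiments need. It is *not* a
population-genetic simulation: no recombination maps, no mutation-drift
site-frequency spectrum, no population structure or pedigree, and the LD
it produces is stationary along the genome. Conclusions drawn from it
about *relative* method behavior transfer; absolute accuracies do not.

`simulate_trait()` supports four architectures: a single QTN; a
normal-mixture architecture whose effect-size classes mirror the BayesR
variance classes; an additive-plus-dominance architecture; and a
liability-threshold case-control trait. The residual is orthogonalized
against the genetic values and rescaled so the realized variance ratio
equals the target heritability *exactly on the simulated cohort* (and is
exactly zero when $h^2 = 1$); this makes heritability invariants testable
without sampling slack and matches how the package defines $h^2$
throughout: as a realized variance ratio, not a population parameter. The
single-QTN effect is fixed at 1, which is scale-free after the $h^2$
normalization.

## Problem sizes and designs used by the checks

The quantitative checks run at desk scale, chosen so each captures the
phenomenon it tests:

- *QTN-only prediction*: $n = 500$; a fully heritable single-QTN trait
  predicted from a panel holding only the QTN gives pooled cross-validated
  accuracy 1 (the acceptance script reports it as a percentage).
- *$\sqrt{h^2}$ law*: the expectation
  $\mathrm{Cor}(\mathrm{EBV}, y) = \sqrt{h^2}$ presumes EBVs estimated
  with negligible error, as in large, strongly related breeding
  populations. The check therefore uses a strongly related cohort —
  copying-chain LD `ld_rho = 0.998`, $n = 1000$, $m = 2000$, MAF 0.3–0.5,
  a purely polygenic trait (the infinitesimal architecture GBLUP assumes)
  — where the effective number of independent segments is far below
  $n h^2$ and the premise holds. With weak LD the same law is *not*
  observable at this $n$: accuracy is then bounded near
  $h \sqrt{n h^2 / (n h^2 + M_e)}$, an expected and informative failure,
  not a defect of the estimator. Five CV replicates per heritability
  level.
- *REML recovery*: 20 trait replicates on one $n = 1000$, $m = 2000$
  panel.
- *Density-shape study*: $n = 800$, $m = 5000$, `ld_rho = 0.8`, densities
  1–5000, two CV replicates, and three independent nested panel draws per
  density with the spread across draws as the uncertainty — for a
  deterministic method the CV-replicate spread cannot see
  panel-composition luck, which dominates at low densities. At this $m$
  the QTN-excluded curve levels off at the top of the grid; the
  QTN-included curve is still in its dilution regime when the panel is
  exhausted, so its top-of-grid flattening is the weakest of these checks
  and can fall outside a strict two-standard-error band.
- *MAF-by-method interaction*: the skewed-trait setting — $n = 300$,
  liability case-control (prevalence 0.08, liability $h^2 = 0.7$, two
  large QTL plus a small-effect tail) on 400 common markers, plus 5,000
  null markers at MAF 0.01–0.02; thresholds 0.01 vs 0.2 with matched-size
  random controls; BayesR deliberately run on a tight budget (1,500
  iterations) because an under-resourced chain at high marker count is
  part of the mechanism being reproduced.

## Known limitations

- The dense REML backend is $O(n^3)$ per iteration and intended for
  cohorts up to a few thousand; no sparse or low-rank solvers are
  provided.
- Mean imputation is the only missing-genotype treatment; multi-allelic
  sites, phasing and genotype likelihoods are out of scope.
- The Gibbs sampler is single-chain; the Geweke flag detects
  non-stationarity but no cross-chain diagnostic is computed.
- The simulator's LD chain has a single parameter and no demographic
  interpretation; simulated minor-allele-frequency spectra are uniform by
  construction.
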