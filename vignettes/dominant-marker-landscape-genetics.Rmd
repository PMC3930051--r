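---
title: "Methods: dominant-marker landscape genetics with aflpscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dominant-marker landscape genetics with aflpscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(aflpscape)
```

`aflpscape` analyses binary dominant-marker data (AFLP-style band
presence/absence) from populations sampled along environmental gradients.
This vignette is the package's own account of the statistical models it
implements, the tunable parameters that matter, what the synthetic-data
generator does and does not emulate, and the numerical and design choices
made where the methodology was genuinely open.

## The dominance model

Everything starts from Hardy–Weinberg dominance: at a biallelic locus with
band (dominant) allele frequency $p$ and null allele frequency $q = 1-p$, an
individual lacks the band only when homozygous null, so the absent count
among $n$ scored individuals is $\mathrm{Binomial}(n, q^2)$. Two estimators
of $q$ are provided:

* `sqrt` — $\hat q = \sqrt{\text{absent}/n}$, the method-of-moments inverse.
  This is the default for diversity statistics (`uHe`, Nei distances,
  percent polymorphic), matching the convention of the common
  dominant-marker calculators.
* `bayes_uniform` — the posterior mean of $q$ under a uniform prior,
  evaluated by adaptive quadrature (relative tolerance $10^{-8}$, cached per
  $(\text{absent}, n)$ pair). This estimator is strictly inside $(0,1)$ for
  partial counts and is used inside the F_ST machinery, whose lineage of
  tools uses Bayesian dominant-data estimators. The two estimators converge
  as $n$ grows; the test suite checks agreement to $10^{-3}$ at $n = 10^5$.

Using each estimator where its tool tradition uses it — rather than one
estimator everywhere — was a deliberate per-stage-fidelity decision.

Within-population inbreeding is assumed absent ($F_{IS} = 0$): the $2pq$
heterozygosity formula and the binomial dominance likelihood both rest on
HWE. No Lynch–Milligan small-sample correction is applied by default, since
`uHe`'s $2n/(2n-1)$ factor is the only finite-sample adjustment the
downstream statistics expect.

## Diversity, distances, AMOVA

A locus is polymorphic in a population when $\hat p$ lies strictly inside
$(1-\ell, \ell)$ with $\ell = 0.99$ (the "99% criterion"). Nei's standard
distance treats each locus as biallelic with the estimated $(p, q)$ pair and
accumulates $J_{xy}, J_x, J_y$ over jointly scored loci; a pair sharing no
allele would give infinite distance and is capped (default 30). UPGMA trees
are built on these distances with ties broken by lexicographic population
order, and node support comes from resampling **loci** with replacement
(the data unit the band matrix actually samples independently), not
individuals. Supports are therefore invariant to locus order only in
distribution; the suite checks topology invariance exactly and supports at
bootstrap precision.

AMOVA works on squared inter-individual distances: the count of differing
loci over jointly scored loci, rescaled by the total locus count, which is
unbiased under missing-at-random scoring failures. Variance components
equate observed mean squares to expectations with the standard
unequal-sample-size coefficients; negative component estimates are retained
(they are sampling noise) and only clamped downstream at linearization.
Permutation schemes match each statistic: individuals among populations
(Φ_ST), whole populations among groups (Φ_CT), individuals among
populations within groups (Φ_SC), with $p = (1 + \#\{ \text{perm} \ge
\text{obs}\})/(B+1)$. With two groups the Φ_CT permutation space is small
(36 distinct assignments of nine populations into 2+7), so its p-values are
coarse — a property of the design, not the implementation.

Cluster labels are taken as explicit input everywhere. When none exist, a
clearly labelled **surrogate** (`assign_clusters`) runs k-means on
population band-frequency vectors over $K = 2..6$, picks $K$ by mean
silhouette width, and flags a population admixed when its
nearest/second-nearest centroid distance ratio exceeds 0.8. The ratio uses
leave-one-out centroids: without that, an intermediate population drags its
own cluster's centroid toward itself and masks its intermediacy. This
surrogate stands in for external Bayesian clustering software; analyses of
real data should pass the externally derived labels instead, and whether an
admixed population is pooled with a particular cluster in hierarchical
AMOVA is left to the caller.

## Distance mixed models and their bootstrap

The isolation-by-distance/adaptation analysis regresses linearized genetic
distance $\Phi/(1-\Phi)$ (Φ clamped to $[0, 0.999]$ first) on ln great-circle
kilometres (floored at 0.1 km so co-located sites stay finite) and on
Euclidean environmental distance over the first $k$ axes (default 4) of a
correlation-matrix PCA of the site variables. Because coarse cluster
structure can masquerade as both effects, the model adds the pair category
as a grouping variable:

$$y_{ij} = \mathbf{x}_{ij}^\top \beta + u_{c(ij)} + \varepsilon_{ij},
\qquad u_c \sim N(0, \sigma_u^2), \; \varepsilon \sim N(0, \sigma^2).$$

Categories default to three pooled levels — within-cluster, between-cluster,
admixed-involved — because three levels is already few for a variance
estimate; a finer five-level split is a config option, as is a fixed-effect
category mode for sensitivity analysis. Estimation is maximum likelihood
(not REML: the bootstrap compares fixed-effect structures, and ML
likelihoods are the comparable ones). Both $\beta$ and $\sigma^2$ profile
out analytically after rotating by the eigenvectors of $ZZ^\top$, leaving a
one-dimensional bounded optimisation over $\lambda = \sigma_u^2/\sigma^2$
(on the log scale, tolerance $10^{-10}$, with the boundary $\lambda = 0$
checked explicitly). The fit is verified in the tests against a dense-GLS
likelihood oracle to $10^{-6}$ and against an independent mixed-model
implementation. $R^2$ is the squared correlation of observed and fitted
values, with fitted values including predicted (BLUP) category effects.

Significance of added fixed effects uses a parametric bootstrap: fit the
reduced model, simulate the response from it ($u^*$ and $\varepsilon^*$
fresh each replicate), refit both models, and compare the observed
$2\Delta\ell$ with the simulated distribution. Simulated likelihood-ratio
statistics are clamped at zero (boundary noise). The test suite checks the
null calibration (uniform p-values by Kolmogorov–Smirnov over 200 outer
replicates at $B = 199$) and power at a planted environmental slope.

MRM unfolds lower triangles and fits OLS, with significance from
simultaneous row/column permutation of the response matrix. Partial Mantel
tests residualize both matrices on the controls and permute the
residualized first matrix (the residual-permutation variant, chosen because
the classical label permutation has inflated size with autocorrelated
controls). The cluster control matrix codes 0 within, 1 between; pairs
involving an admixed population get 0.5 (configurable), a neutral choice
given the population's mixed ancestry.

## The three candidate-locus scans

**Envelope scan.** Per-locus F_ST comes from a Weir–Cockerham-form moment
estimator applied to the Bayesian allele-frequency estimates, with the
per-population scored count `n_eff` as the weight — for dominant data one
individual carries roughly one allele's worth of information, so individual
counts, not $2n$, are the honest weights. The neutral reference replaces a
coalescent engine with a symmetric Beta-model island approximation:
ancestral frequency uniform on $(\theta_{\min}, 1-\theta_{\min})$,
population frequencies Balding–Nichols with differentiation $F$, dominant
phenotypes binomially sampled at the observed sample sizes, and the same
estimation path (including the polymorphism screen) as the real data. $F$
is calibrated by bisection (18 iterations, 4000-locus pilot batches) so
the simulated mean F_ST matches the observed untrimmed mean. The scan
config accepts the conventional scaled-diversity parameter `theta`
(default 0.018) and uses it as the polymorphism-conditioning floor of the
simulated ancestral frequencies, consistent with reports that results are
insensitive to it over an order of magnitude. The envelope is the upper
0.99 conditional quantile of F_ST given He, computed in ~20 merged He bins
(each at least 1000 simulated loci) and isotonically smoothed in He, since
the attainable F_ST range grows with diversity. Only upper-tail (divergent)
candidates are flagged; the lower envelope is reported for information. The
per-locus *p* is the neutral tail mass within the locus's He bin — the
quantile-exceedance semantics the tool lineage leaves undefined. With
`iterate_removal`, candidates are removed, the target mean recomputed, and
the scan repeated (≤5 rounds): removing top loci necessarily lowers the
recalibrated mean, which slightly inflates the neutral flag rate above the
nominal 1%; the test suite checks that the 20-replicate average stays
inside a 0.5–2% band — the price of the iterative trimming logic.

**Bayesian decomposition.** $\mathrm{logit}(F_{ij}) = \alpha_i \delta_i +
\beta_j$ with $p_{ij} \sim \mathrm{Beta}(\theta_{ij} p_i, \theta_{ij}(1 -
p_i))$, $\theta_{ij} = (1-F_{ij})/F_{ij}$, and absent counts binomial in
$(1-p_{ij})^2$. Priors: $\alpha_i \sim N(0,1)$, $\beta_j \sim N(-1,1)$,
prior inclusion odds 1:10 (all configurable — the published model family
states no hyperparameters). Latent frequencies and ancestral frequencies
update by logit-scale random walks with pilot adaptation toward 30%
acceptance during burn-in; the locus effects toggle by reversible jump,
proposing $\alpha$ from its prior so the proposal ratio cancels. The
q-value of a locus is the mean of $1-\mathrm{PIP}$ over loci ranked at or
above it, monotone by construction; candidates have $q \le 0.05$. With
two chains (the default) a split-$\hat R$ on the population effects above
1.2 attaches a mixing warning. Defaults are 10,000 iterations, 2,000
burn-in, thinning 10.

**Association scan.** For every polymorphic locus × predictor (site-level
environmental PCA axes broadcast to individuals), a univariate logistic
regression by IRLS (tolerance $10^{-8}$); significance requires **both**
the Wald and the likelihood-ratio G test below $\alpha/m$ with $m =
\text{loci} \times \text{predictors}$ ($\alpha = 0.01$). The scan runs on
polymorphic loci only — that is what makes the family size come out as
loci × axes. Complete separation (divergent slope, |slope| > 15 or
exploding SE) flags the locus unstable and excludes it from the
significant set rather than reporting a meaningless p-value.

Consensus tables flag each locus per method; the locus–trait stage prunes
redundant traits greedily (drop the trait with the larger mean absolute
correlation while any pair exceeds $r = 0.7$), computes Pearson
correlations between candidate-locus band frequencies and population trait
means, and corrects by Holm (chosen over Bonferroni as the uniformly more
powerful step-down procedure consistent with an unspecified "multiple
comparisons correction"; Bonferroni is a flag away).

## What the generator emulates — and what it does not

`sim_config()` defaults define the study conditions: 2 clusters × 4
populations plus one admixed population (a 50/50 frequency mixture of the
two populations flanking the contact zone — individual-level admixture is
out of scope), 15 individuals each, 229 loci, $F_{CT} = 0.08$, $F_{SC} =
0.06$, ancestral frequencies uniform (giving roughly 60–65% polymorphic
loci per population at these sample sizes), 2% missing data, 15 replicate
pairs flipped at 0.78%, five loci under divergent selection with logit
slope 2 along the standardized gradient, and phenotype tables for an
insect-free net-house and a common-garden experiment. Trait means are
linear in the gradient plus a locus term for the two designated trait–locus
pairs (stem trichomes in the net house, late herbivory in the common
garden), with per-trait residual scales matched to each trait's
measurement scale (days, centimetres, 0–5 scores; `noise_sd` scales them
globally) so that traits driven by the same gradient correlate realistically
rather than collinearly. The two-level Balding–Nichols cascade was chosen
over coalescent simulation because it reproduces exactly the moment
structure AMOVA and F_ST measure, at negligible cost and fully seeded.

Not emulated: linkage disequilibrium between loci, spatially explicit
dispersal, individual-level admixture, within-population inbreeding, or
scoring artefacts beyond symmetric flips and missing-at-random masking.
Passing calibration and power tests on these data therefore says the
estimators and their inference are internally correct under the model the
field's analyses themselves assume — not that real AFLP data meet those
assumptions.

## Numerical choices and problem sizes

Sub-seeds for each generator stage derive deterministically from the config
seed, so a dataset is byte-identical across calls while stages stay
independently reusable. Degenerate paths are explicit: $F = 0$ copies
frequencies without a Beta draw; identical individuals give zero AMOVA
components and Φ_ST = 0 by convention; an exactly duplicated population has
slightly **negative** expected pairwise Φ_ST ($-1/(n-1)$), which the tests
treat as near zero rather than exactly zero. PCA axes follow a
deterministic sign convention (largest-magnitude loading positive).
Quadrature for the Bayesian $q$ estimator is log-scaled to survive large
$n$.

The test suite runs its calibration studies at sizes chosen to finish in
minutes on one core while keeping Monte-Carlo error well inside the asserted
bands: 20 neutral replicates × 10,000 envelope simulations for the flag
rate; 200 outer × 199 inner replicates for the bootstrap-LMM null; 100
replicates for the planted-β power; 25 and 15 replicates for envelope and
consensus power; 20 replicates with 2,000-iteration chains for the Bayesian
FDR check. The locus–trait recovery check asserts a floor below the
asymptotic recovery rate because with only nine populations the redundancy
pruning occasionally removes the linked trait itself — a real feature of
such small designs.

## Known limitations

* Φ_CT inference is granular with few populations per group (a permutation
  limitation, not an implementation one).
* The envelope scan's neutral model is an island approximation; under
  strong hierarchical structure its false-positive rate rises, which is
  visible in the package's own simulations and consistent with what is
  reported for the tools it models.
* The Bayesian scan's q-values depend on chain mixing; short chains warn
  via split-$\hat R$ but are not refused.
* Nine sites give at most eight informative PCA axes and n = 36 pairwise
  distances; all matrix-based inference here lives in that small-n regime,
  and the permutation p-values inherit its granularity.
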