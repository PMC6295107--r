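---
title: "Detecting epistasis in survival data with Cox UM-MDR"
author: "coxummdr package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting epistasis in survival data with Cox UM-MDR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coxummdr)
```

## The problem

Single-SNP association scans leave much of the heritability of complex
traits unexplained; one candidate reservoir is epistasis — joint effects
of SNP pairs that are invisible marginally. Multifactor dimensionality
reduction (MDR) searches for such pairs by collapsing the $3^k$ genotype
cells of a $k$-SNP combination into a one-dimensional high/low-risk
attribute. For a censored survival phenotype the natural classification
signal is the martingale residual of a Cox model: subjects who die
earlier than the null model predicts carry positive residuals.

The catch is inference. Classical survival MDR (Cox-MDR) selects the
best pair by cross-validated balanced accuracy and then needs a full
permutation test for significance, which is expensive at genome scale.
Cox UM-MDR instead tests the constructed risk attribute inside a
standard Cox model and repairs the null distribution analytically.

## The two-step procedure

**Step 1 (classification).** Compute martingale residuals
$M_i = \delta_i - \hat\Lambda_0(t_i) e^{\hat\eta_i}$ under a null Cox
model fitted without any genetic terms. For each SNP combination, label
a genotype cell high-risk when the sum of its members' residuals is
strictly positive (ties and empty cells are low-risk), and set the
subject-level indicator $S_i = 1$ for members of high-risk cells.

**Step 2 (testing).** Fit
$\lambda(t \mid S, Z) = \lambda_0(t)\exp(\beta S + \gamma' Z)$ and test
$H_0:\beta = 0$ with the Wald statistic $W = \hat\beta^2 /
\widehat{Var}(\hat\beta)$. Because $S$ was built from the same outcome,
$W$ is stochastically larger than a central $\chi^2_1$ under the null:
its asymptotic null law is a non-central $\chi^2_1(q)$. Since
$E[\chi^2_1(q)] = q + 1$, a handful of trait permutations (default
$B = 5$) that re-run both steps yield $\hat q = \max(0, \bar W^{perm} -
1)$, and the corrected p-value is the upper tail of $\chi^2_1(\hat q)$
at the observed $W$. The non-centrality can be estimated per
combination (default) or pooled across all combinations.

Permutations shuffle the (time, status) pairs jointly against the fixed
(genotype, covariate) rows. In the baseline-only step-1 mode the
residual vector depends on (time, status) alone, so each permutation
simply permutes the residuals — the classification is still re-run, as
it must be for the non-centrality logic to make sense.

## The step-1 null model: a deliberate choice

Both step-1 conventions are implemented, switched by
`ummdrControl(adjustCovariatesStep1 = )`:

* `FALSE` (default): residuals from the baseline-hazard-only model, the
  literal "null Cox model with no covariates".
* `TRUE`: residuals from a covariate-adjusted null model — the
  convention of the original Cox-MDR classifier.

The distinction matters when covariates carry real signal. With a
strong covariate ($\gamma = 1$), baseline-only residuals are dominated
by covariate-driven variation; the MDR cells then partially encode the
covariate, which the step-2 model reabsorbs through $\gamma' Z$,
attenuating the selection inflation. Covariate-adjusted residuals make
the classification operate on outcome noise alone, which is both the
behaviour Cox-MDR's classifier was designed for and the configuration
under which our simulation harness reproduces the published
family-wise raw type-I error of roughly 0.41 at MAF 0.2 (baseline-only
gives roughly 0.20 there). The package's simulation studies and
acceptance checks therefore run with `adjustCovariatesStep1 = TRUE`;
the default remains the literal baseline-only reading for users who
want it.

## Simulation machinery

The generator reproduces the conditions of the published simulation
study:

* **Genotypes.** 10 unlinked diallelic SNPs under HWE and linkage
  equilibrium, minor allele frequency shared within a scenario.
* **Penetrance models.** Two-locus tables $f_{ik} = P(\text{high risk}
  \mid SNP1 = i, SNP2 = k)$ with prescribed heritability $h^2 = \sum
  P(G_{ik})(f_{ik} - K)^2 / K(1-K)$ and *no* single-locus marginal
  effect. Tables are found by projecting a random table onto the
  pure-interaction space (under HWE cell weights) and rescaling about
  the prevalence $K$ to hit $h^2$ exactly; $K$ itself is drawn
  uniformly on (0.05, 0.95) per proposal since the source catalogue's
  prevalences are not published. Out-of-range proposals are rejected.
  The specific published catalogue of 70 tables is not printed
  anywhere accessible, so fresh tables at the same 14 (MAF, $h^2$)
  combinations stand in for it; power magnitudes may shift slightly,
  trends should not.
* **Survival.** $\lambda(t \mid x, z) = \lambda_0(t)\exp(\alpha x +
  \gamma z + \delta\,SNP3)$ with $\alpha = \gamma = 1$, $x \sim
  \mathrm{Bern}(f_{g_1 g_2})$ the latent high-risk state, $z \sim
  N(0,1)$, and $\delta = 0.5$ only in the marginal-effect scenario.
  The baseline is Weibull with shape 5 and scale 2, parameterized as
  $\Lambda_0(t) = (t/2)^5$, inverted exactly:
  $T = 2(-\log U\, e^{-\eta})^{1/5}$.
* **Censoring.** $C \sim U(0, c)$ with $c$ calibrated by bisection on a
  Monte-Carlo estimate (50,000 draws, tolerance 0.005 on the achieved
  fraction) to hit target fractions 0, 0.1, 0.3, 0.5. A target of 0
  disables censoring. Calibration is done once per scenario and reused
  across replicates.
* **Null cohorts** for type-I error use the same design with $\alpha =
  0$: survival depends only on $z$.

What the generator does *not* emulate: linkage disequilibrium,
population structure, genotyping error, informative censoring, and
covariate-SNP interaction. Conclusions from passing tests therefore
speak to the method's operating characteristics under clean HWE
cohorts, not to robustness against those features of real data.

## The Cox-MDR comparator

The comparison baseline reconstructs classical Cox-MDR: 10-fold
cross-validation stratified by event status; cells labeled from
training-fold residual sums; per-subject pseudo-class $c_i = 1\{M_i >
0\}$; testing score = balanced accuracy of the predicted $S$ against
$c$ on the held-out fold; the best pair maximizes the mean testing
score, ties broken by cross-validation consistency and then
lexicographically. The cited description of the original method does
not restate its exact CV statistic, so this balanced-accuracy
reconstruction (the GMDR-style generalization with residual sign in
place of case/control status) is our design choice; quantitative
divergences from the published power curves are attributable to this
gap. Empty training cells predict low risk; a class absent from a test
fold contributes chance-level recall 0.5.

## Experiment harnesses and their scale

`runTypeIGrid()` measures family-wise error over the 45-pair scan:
a replicate rejects when its smallest p-value falls below
$\alpha/45$ (Bonferroni), with the raw rate using central-$\chi^2_1$
p-values and the corrected rate the non-central ones. The published
grid is 5 MAFs $\times$ 4 censoring fractions $\times$ 1000 null
replicates of $n = 400$; the full grid runs in roughly a quarter hour
on one core. `runPowerGrid()` measures `PBonf` (causal pair
Bonferroni-significant at 0.05), `PRank` (causal pair ranked first by
corrected p-value) and the Cox-MDR selection frequency, 100 replicates
per grid point by default. The package's own test suite runs the full
type-I grid and a single representative power point (MAF 0.2,
$h^2 = 0.4$, both scenarios) to keep the default check fast;
`inst/scripts/cox-ummdr` exposes the complete grids.

## Numerical choices

* Ties: Breslow everywhere (partial likelihood, baseline hazard,
  residuals). This makes baseline-only residuals sum exactly to zero
  and keeps all components internally consistent.
* The Cox fitter is a Newton solver with step halving, score tolerance
  $10^{-8}$, relative log-likelihood tolerance $10^{-10}$, at most 50
  iterations; monotone likelihood (separation) is reported as
  non-convergence with coefficients capped at $\pm 15$. It matches
  `survival::coxph(ties = "breslow")` to $10^{-6}$ and a brute-force
  partial-likelihood grid search to $10^{-3}$ in the test suite.
* Degenerate combinations (indicator constant, e.g. monomorphic SNPs)
  are reported with p-value 1 and a flag rather than dropped, keeping
  ranks comparable across replicates.
* A combination with no informative permutation replicate gets
  $\hat q = 0$ (no correction) rather than an error.
* Missing genotypes exclude a subject from the affected combination
  only (per-combination complete case); sample alignment in file input
  is always by sample id, never row order.
* Seeds: every randomized operation derives per-unit seeds from the
  `ummdrControl(seed = )` stream, so results are bit-identical across
  re-runs and independent of execution order.

## Known limitations

* The non-centrality estimate from $B = 5$ permutations is noisy
  (roughly $SD(\hat q) \approx \sqrt{2(1+2q)/5}$); the corrected test
  tends to be conservative at high MAF, where the classification
  inflation $q$ is largest. Pooling (`noncentrality = "pooled"`)
  trades per-combination adaptivity for stability.
* The published raw (uncorrected) family-wise error rates are matched
  closely at intermediate MAF but our implementation shows a steeper
  MAF dependence at the extremes (lower at MAF 0.05, higher at MAF
  0.4) under every step-1/step-2 configuration we examined; the fast
  scan path is verified against an independent `survival::coxph`
  reimplementation, so this reflects an unstated implementation detail
  of the original classifier rather than a defect in either Cox
  engine.
* Higher-order scans ($k > 2$) are supported by the same machinery but
  untested against any published reference; cells get sparse quickly.
* No LD pruning, imputation or PLINK/VCF ingestion — genotypes arrive
  as additive-coded TSV matrices.
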