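---
title: "Variance-component structural equation models on genomic-relationship matrices"
author: "gsemkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variance-component structural equation models on genomic-relationship matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsemkit)
```

## The problem

Longitudinal developmental traits — here the motivating example is vocabulary
size measured repeatedly across toddlerhood, followed by reading and IQ in
mid-childhood — are each modestly heritable, but the scientific question is
*structural*: are the genetic influences at different ages the same factor
expressed repeatedly, or do new genetic factors come online as development
proceeds, and which of them carry forward into later-life skills?

In classical twin designs this question is answered with a Cholesky
decomposition: as many latent genetic factors as traits, loading
lower-triangularly in chronological order. `gsemkit` implements the analogue
for *unrelated* individuals, where latent genetic factors are identified not
through twin resemblance but through the genomic-relationship matrix (GRM)
computed from genome-wide SNPs.

## The model

Let $A$ be the $n \times n$ GRM, estimated from standardized dosages as

$$A_{jk} = \frac{1}{M_{jk}} \sum_{i=1}^{M} \frac{(x_{ij} - 2p_i)(x_{ik} - 2p_i)}{2 p_i (1 - p_i)},$$

with pairwise-complete marker counts $M_{jk}$. For $m$ traits stacked
trait-major into one vector, the Cholesky GSEM assumes

$$\mathrm{Cov}(y) \;=\; (\Gamma\Gamma^\top) \otimes A \;+\; (\mathrm{E}\mathrm{E}^\top) \otimes I_n ,$$

where $\Gamma = (a_{ij})$ and $\mathrm{E} = (e_{ij})$ are lower-triangular
$m \times m$ path matrices: genetic factor $j$ loads on traits $i \ge j$ with
coefficient $a_{ij}$, and residual factors (untagged genetic variation,
environment, measurement error) do the same through $e_{ij}$. The mean is
fixed at zero because the model is fitted to covariate-adjusted, rank-based
inverse-normal-transformed residuals, which have exactly zero mean and unit
variance per trait.

Missing assessments are handled by *selection*, not deletion: the likelihood
uses the observed rows/columns of the big covariance, so every available
observation contributes. Estimation is by full maximum likelihood over the
$m(m+1)$ free paths (a design choice — the univariate ML/REML gap at these
sample sizes is well below the estimation error, and the package's own
GSEM-vs-GREML consistency check bounds it at 0.02 on $h^2$).

Two likelihood routes give identical values (tested to $10^{-8}$ against a
brute-force dense Gaussian density):

* **complete data** — rotate by the GRM eigenbasis $A = U D U^\top$;
  after simultaneous diagonalization of $\mathrm{E}\mathrm{E}^\top$ and
  $\Gamma\Gamma^\top$ the likelihood factorizes over eigenvalues into
  $m$-dimensional terms, $O(nm^2)$ per evaluation. The eigendecomposition can
  be cached and shared across phenotype replicates.
* **missing data** — dense Cholesky factorization of the observed-block
  covariance, $O(N_{obs}^3)$; intended for desk-scale $n \cdot m \lesssim 10^4$.

Sign identification: flipping the sign of a whole factor column leaves the
likelihood invariant, so fitted models are reported with non-negative
diagonals. An identity-like GRM (numerically flat eigenvalue spectrum)
identifies only the *total* covariance, not the genetic/residual split; the
fit flags this instead of returning an arbitrary decomposition.

## GREML (the univariate and bivariate comparator)

`fitUnivariateGreml()` estimates $V = \sigma^2_g A + \sigma^2_e I$ by
average-information REML with an intercept as fixed effect. In the GRM
eigenbasis each iteration is $O(n)$. Iterations use step halving on the
restricted likelihood, variance components are kept above $10^{-6}$ of the
phenotypic variance (boundary projection; an unconstrained option exists),
and convergence is a relative log-likelihood change below $10^{-8}$ or 100
iterations. Standard errors come from the inverse AI matrix, the $h^2$
standard error by the delta method, and the test of $\sigma^2_g = 0$ uses the
boundary likelihood-ratio mixture $\tfrac12\chi^2_0 + \tfrac12\chi^2_1$.
`fitBivariateGreml()` generalizes this to six components (two genetic
variances, a genetic covariance, residual analogues) on the dense stacked
covariance of two overlapping, possibly differently-missing trait vectors,
and reports $r_g$ with a delta-method SE.

Traits are screened before multivariate modelling: those without nominal
univariate heritability evidence (LRT $p \ge \alpha$, default
$\alpha = 0.05$) are excluded and logged, which mirrors standard practice and
helps the multivariate fit converge.

## Derived statistics

All are functions of the standardized paths (each trait's loadings divided by
its total implied SD):

* **variance explained** per factor: $a_{ij}^2$ (negative estimates square in
  as-is);
* **SNP-$h^2$**: $\sum_j a_{ij}^2 / (\sum_j a_{ij}^2 + \sum_j e_{ij}^2)$ —
  for the first trait this is exactly $a_{11}^2$;
* **genetic / residual correlations**: correlation matrices of
  $\Gamma\Gamma^\top$ and $\mathrm{E}\mathrm{E}^\top$;
* **factorial co-heritability**: $a_{ij}^2 / \sum_{j'} a_{ij'}^2$, the share
  of a trait's genetic variance owned by one factor (rows sum to 1);
* **bivariate heritability**: $\sum_j a_{ij} a_{kj} / r_p(i,k)$, the share of
  an *observed* phenotypic correlation accounted for by model-implied genetic
  covariance (the observed $r_p$ is used deliberately, not the model-implied
  one).

Standard errors for any scalar derived statistic are first-order delta-method
propagations of the free-path covariance (inverse numerical Hessian, central
differences, relative step $10^{-4}$); a parametric bootstrap
(`bootstrapSE()`) is provided as a cross-check and agrees within ~15%
relative in the package's tests.

## Tunable parameters

| Parameter | Default | Notes |
|---|---|---|
| SNP QC: MAF / call rate / HWE $p$ | 0.01 / 0.99 / $5\times10^{-7}$ | HWE is a 1-df chi-square on genotype counts |
| relatedness cutoff | 0.05 | see scaling note below |
| screening $\alpha$ | 0.05 | applied to the boundary-LRT $p$ |
| INT offset | $r/(n+1)$ (van der Waerden) | Blom $(r - 3/8)/(n + 1/4)$ optional |
| ancestry PCs | 2 | eigenvectors of the GRM |
| GSEM start | $\sqrt{h^2_{GREML}}$, $\sqrt{1-h^2}$ diagonals, 0.05 off-diagonals | small positive off-diagonals avoid the saddle at zero |
| optimizer | BFGS, central-difference gradients, reltol $10^{-12}$ | restarted once on non-convergence |

**Relatedness-cutoff scaling.** The off-diagonal entries of a null GRM have
standard deviation $1/\sqrt{M}$. With genome-wide panels
($M \approx 5\times10^5$) the noise floor is $\approx 0.0015$ and a cutoff of
0.05 isolates genuinely related pairs. With the small marker panels used in
simulation ($M$ in the hundreds or low thousands) the noise floor is 0.02 to
0.04 and a 0.05 cutoff would remove nearly everyone; the worked examples and
validation runs therefore use 0.25, which sits at the same distance above
noise. The pruning operation itself is cutoff-agnostic and guarantees its
post-condition (no remaining pair at or above the cutoff) at any value.

**Covariate recipes.** Early-life traits are adjusted for sex, assessment
age, age squared (development is fast and nonlinear at these ages) and two
ancestry PCs; reading for sex, age and PCs; IQ measures, which are
age-normed by construction, for sex and PCs only. Adjustment precedes the
rank transformation.

## The synthetic cohort generator

`simulationSpec()` describes a cohort by its ground truth: per-SNP allele
frequencies uniform in `mafRange`, Binomial(2, $p$) dosages, explicit per-SNP
effects with variance $1/M$ per genetic factor (so the same genotypes flow
into GRM construction and phenotype generation — the causal chain
genotype → GRM → phenotype is preserved rather than sampling phenotypes from
the GRM directly), residual factors iid normal, sex/age/age² covariate
effects, and per-trait completely-at-random missingness (a monotone-dropout
flag exists).

The four-trait default emulates a longitudinal vocabulary cohort: implied
SNP-$h^2$ of 0.109 / 0.147 / 0.160 / 0.121, phenotypic correlations 0.53
between the first two waves and 0.63 between the two same-age measures, and
missingness rates (0, 0.08, 0.07, 0.07) that reproduce observed wave sizes of
6,524 / ~6,014 / ~6,092 at full cohort scale. `outcomeTruthModel()` appends a
mid-childhood outcome row (reading-, VIQ- or PIQ-like loadings of
0.25–0.60 on the second and fourth factors, with near-zero residual
covariance to the fourth trait so that phenotypic correlation is mostly
genetic).

What the generator does **not** emulate: linkage disequilibrium, population
structure and admixture, assortative mating, indirect (parental) genetic
effects, instrument ceiling effects, and whatever non-random attrition
process shapes a real cohort's missingness. Passing recovery tests therefore
demonstrate that the estimators are correct *under the model's own
assumptions* at realistic effect sizes — they do not certify robustness to
these real-data complications.

## Validation design and problem sizes

The package validates itself at desk scale, chosen so the full suite runs in
minutes: univariate calibration at $n = 1000$, $M = 2000$ (500 null
replicates for the boundary LRT's type-I error), four-trait path recovery at
$n = 2000$, $M = 2000$ (200 phenotype replicates), and oracle comparisons at
$n \le 200$. Replicate batches redraw phenotypes on one fixed genotype panel
with a cached GRM eigendecomposition; calibration statements are therefore
conditional on a realized GRM, which is the standard conditioning for REML
inference.

## Numerical and degenerate-input policy

* Non-positive-definite implied covariances return `-Inf` from the
  likelihood (optimizer-safe) rather than erroring.
* AI-REML steps that fail positive definiteness or decrease the restricted
  likelihood are halved up to 30 times; a fit that cannot move uphill stops
  and reports its last iterate.
* Rank transformation of an all-constant vector, QC that removes every SNP,
  bivariate fits with no overlapping individuals, and GRM file size
  mismatches are explicit errors with named causes.
* A Hessian that is not positive definite at the optimum suppresses standard
  errors (with a warning and the condition number as a diagnostic) instead of
  producing imaginary ones.

## Known limitations

* **Boundary bias near null factors.** When a trait's own genetic factor is
  (near) zero, its folded estimate absorbs a little genetic variance from
  earlier factors in the same row: neighbouring paths acquire a small
  downward bias (about 0.02 at $n = 2000$ in the four-trait default) and
  their Wald coverage dips slightly below nominal in small replicate
  batches. This is a property of the Cholesky parameterization at the
  boundary, not of the optimizer; profile-likelihood intervals would be the
  remedy but are not implemented.
* **Exactly duplicated traits** drive the bivariate REML to a singular
  boundary ($r_g \to 1$, diverging likelihood); the fit stops at its guard
  and the correlation limit, not the component values, is the stable
  quantity.
* Wald (normality-based) confidence intervals throughout; no
  profile-likelihood option.
* Single-GRM models only: no GxE, dominance, multi-component GREML, or
  common/independent-pathway structures.
* The greedy pruning rule guarantees the relatedness post-condition but not
  a maximum retained sample (minimum vertex cover is NP-hard; greedy
  max-degree removal is the documented heuristic).
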