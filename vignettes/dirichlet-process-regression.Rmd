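---
title: "Latent Dirichlet process regression: model, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent Dirichlet process regression: model, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dpr)
```

## The problem

Polygenic prediction regresses a quantitative trait on all genotyped SNPs
at once. With p often exceeding n, everything rests on the prior placed on
the SNP effect sizes, and most established methods commit to one member of
the scale-mixture-of-normals family: a single normal (LMM/BLUP), a t
(BayesA), a Laplace (Bayesian lasso), a point-normal (BVSR), or a small
finite normal mixture (BayesR). Whichever shape is assumed, traits whose
true architecture differs are predicted suboptimally.

`dpr` removes the parametric commitment. The model is

$$ y = W\alpha + X\beta + \epsilon, \qquad
   \epsilon \sim N(0, \sigma^2_e I_n), $$

with each effect conditionally normal, $\beta_i \mid \sigma^2 \sim N(0,
\sigma^2)$, and the effect-size *variance itself* given a Dirichlet process
prior, $\sigma^2 \sim G$, $G \sim \mathrm{DP}(H, \lambda)$, with
inverse-gamma base distribution $H$. Marginally each $\beta_i$ follows an
infinite normal scale mixture

$$ \beta_i \sim \sum_{k=1}^{\infty} \pi_k\, N(0, \sigma^2_k), \qquad
   \pi_k = \nu_k \prod_{l<k} (1-\nu_l), \qquad \nu_k \sim
   \mathrm{Beta}(1, \lambda), $$

which can take the shape of essentially any zero-mean unimodal effect
distribution, with the number of occupied components inferred from the
data through the concentration parameter $\lambda$.

## Truncation and hyper-priors

Computation uses the blocked stick-breaking representation truncated at a
level $K$ with $\nu_K = 1$, so the weights always sum to one. The default
$K = 4$ is deliberately modest: the posterior occupies only as many
components as the data support, and on every panel we have examined the
occupancy of a fifth component is negligible; $K$ is a user argument for
panels where more resolution is wanted. Remaining hyper-priors, all proper
and weakly informative:

| parameter | prior | default | role |
|---|---|---|---|
| $\sigma^2_k$ | InvGamma($a_\sigma, b_\sigma$) | $a_\sigma = b_\sigma = 0.1$ | base distribution $H$ |
| $\lambda$ | Gamma($a_\lambda, b_\lambda$), shape/rate | $1, 1$ | concentration; conjugate through the sticks |
| $\sigma^2_e$ | InvGamma($a_e, b_e$) | $a_e = b_e = 0.1$ | residual variance |
| $\alpha$ | flat | — | covariates; conditional update is OLS with Gaussian noise |

Genotype columns are centered to their (training) means before fitting;
effects are defined on raw dosages, so centering only shifts the intercept.
We center rather than standardize because the simulator defines effect
scaling on raw dosages, and prediction reuses the stored training means.

## Gibbs sampler (`dpr_mcmc`)

One sweep updates, in fixed order:

1. for each SNP $i$: the component assignment
   $P(\gamma_i = k) \propto \pi_k\, \phi(\beta_i; 0, \sigma^2_k)$ given the
   current $\beta_i$, then
   $\beta_i \mid \gamma_i \sim N(m_i, s^2_i)$ with
   $s^2_i = (x_i^\top x_i/\sigma^2_e + 1/\sigma^2_{\gamma_i})^{-1}$ and
   $m_i = s^2_i\, x_i^\top r_{-i} / \sigma^2_e$, where $r_{-i}$ is the
   running residual with SNP $i$'s contribution added back. The residual is
   updated in place, making a sweep $O(np)$;
2. $\sigma^2_k \sim \mathrm{InvGamma}(a_\sigma + n_k/2,\; b_\sigma +
   \sum_{i:\gamma_i = k} \beta_i^2/2)$ — empty components draw from $H$;
3. $\nu_k \sim \mathrm{Beta}(1 + n_k,\; \lambda + \sum_{l>k} n_l)$ for
   $k < K$, $\nu_K = 1$, weights recomputed;
4. $\lambda \sim \mathrm{Gamma}(a_\lambda + K - 1,\; b_\lambda -
   \sum_{k<K} \log(1-\nu_k))$;
5. $\sigma^2_e \sim \mathrm{InvGamma}(a_e + n/2,\; b_e + \lVert r\rVert^2/2)$;
6. $\alpha \sim N((W^\top W)^{-1} W^\top (y - X\beta),\;
   \sigma^2_e (W^\top W)^{-1})$;
7. record the per-sweep PVE $\mathrm{var}(X\beta) / (\mathrm{var}(X\beta)
   + \sigma^2_e)$ (empirical variance of the fitted genetic values; the
   estimator is a design choice) and the unnormalized log posterior.

Design choices worth stating: single-site updates with residual
bookkeeping rather than joint block draws (standard for this model class
and linear in p); the assignment update conditions on the current
$\beta_i$ rather than marginalizing it — both kernels target the same
posterior, this is the simplest exact one; update order within a sweep is
fixed as listed; burn-in defaults to 20% of the sweeps and thinning to 10;
$\log(1-\nu)$ is clamped at $-700$ so a stick sampled at 1 cannot produce
an infinite rate in the $\lambda$ update. The reference protocol for real
data is 50,000 sweeps (the `dpr_mcmc` and CLI default); the package's test
suite uses hundreds to a few thousand sweeps on panels of tens to hundreds
of SNPs, which those panels mix well within.

Components are label-switching-prone, which is irrelevant for prediction;
for reporting, the posterior inclusion probability of SNP $i$ is the
fraction of kept draws in which $\gamma_i$ is *not* the component with the
smallest variance in that draw, so the "background" is re-identified per
draw rather than per chain.

Correctness is established against independent oracles in the tests: with
$K = 1$ and fixed variances the sampler reproduces the closed-form Gaussian
(ridge) posterior; with $n \le 8$, $p = 2$, $K = 2$ and fixed variances and
weights, the empirical joint posterior over assignments matches dense
numerical integration of the marginal likelihood to within 0.05 in total
variation at $10^5$ sweeps; a debug mode recomputes the residual from
scratch every sweep and stops if the cache drifts beyond $10^{-8}$.

## Variational Bayes (`dpr_vb`)

The mean-field factorization is

$$ q = \prod_i q(\beta_i, \gamma_i) \prod_k q(\nu_k)\, q(\sigma^2_k)
   \cdot q(\sigma^2_e)\, q(\lambda)\, q(\alpha), $$

with a structured per-SNP factor $q(\gamma_i)\, q(\beta_i \mid \gamma_i)$:
$q(\beta_i \mid \gamma_i = k) = N(m_{ik}, s^2_{ik})$ with
$s^2_{ik} = (x_i^\top x_i\, E[1/\sigma^2_e] + E[1/\sigma^2_k])^{-1}$,
$m_{ik} = s^2_{ik}\, E[1/\sigma^2_e]\, x_i^\top E[r_{-i}]$, and
responsibilities
$\phi_{ik} \propto \exp(E[\log\pi_k] - \tfrac12 E[\log\sigma^2_k] +
\tfrac12 \log s^2_{ik} + m_{ik}^2 / 2 s^2_{ik})$, normalized by
log-sum-exp. $E[\log\pi_k]$ comes from digamma functions of the stick Beta
parameters — exact under the factorization. All other coordinate updates
are the conjugate forms with hard counts replaced by expected occupancies
$\sum_i \phi_{ik}$ and squared effects by $\sum_i \phi_{ik}(m_{ik}^2 +
s^2_{ik})$.

Every update is an exact conditional maximizer of the evidence lower
bound, so the ELBO is non-decreasing; the implementation computes the full
bound (including all entropy terms) after each cycle and the tests assert
monotonicity to $10^{-8}$ on every input. Iteration stops when the
relative ELBO change falls below `tol` ($10^{-5}$ by default, at most
1000 cycles); non-convergence returns partial results with a warning,
never silently. Initialization is deterministic — uniform
responsibilities, zero means, variance factors at the prior, $\alpha$ at
the OLS fit — so a converged fit depends only on the data (the `seed`
argument exists for interface parity). With one SNP the factorization is
exact and the converged bound equals the log marginal likelihood; with
$K = 1$ and fixed variances the VB mean solves exactly the ridge normal
equations (Gauss–Seidel fixed point), which the tests check to $10^{-8}$.

The factorization assumes the effect-size posteriors are independent
across SNPs. That is the known weakness of the approximation: with
correlated predictors or strong signal it understates posterior variance
and shrinks the PVE estimate. The tests therefore assert VB/MCMC agreement
(posterior means within 10% relative RMS) only at low heritability, and
the backend comparison in the acceptance script shows VB's PVE sitting
below MCMC's at PVE = 0.5. For high-heritability traits, MCMC is the
recommended backend; VB is the screening tool.

## Genotype input and quality control

PLINK binary (bed/bim/fam, SNP-major) and BIMBAM mean-genotype text are
supported; dosages count copies of the bim file's first allele, recorded
in the container's metadata so effect signs stay interpretable. Missing
genotypes are the bed missing code or the string `NA` in BIMBAM. The QC
filter removes SNPs with HWE $p < 10^{-4}$, call rate $< 95\%$ or MAF
$< 0.01$ (strict inequalities; thresholds configurable), reporting each
removed SNP with the first failing rule in that order. The HWE test is the
1-df chi-square goodness of fit against proportions from the sample allele
frequency — no exact test, and monomorphic SNPs return $p = 1$ so they are
left for the MAF filter. Missing genotypes are imputed with the SNP's mean
observed dosage. Phenotypes can be quantile-normalized to a standard
normal: rank $r$ (average ranks on ties) maps to $\Phi^{-1}((r - 0.5)/n)$.
In cross-validation the normalization map and the centering means are
learned on the training fold only and applied to the test fold by
interpolation, which the tests verify with a mutation check.

## The simulator

`simulate_genotypes` draws per-SNP allele frequencies uniformly on
[0.05, 0.5] and dosages as Binomial(2, MAF), independent across SNPs and
individuals. This emulates an unlinked panel of common variants: it
deliberately reproduces none of the linkage disequilibrium, allele
frequency spectrum or relatedness structure of real cohorts, so passing
tests demonstrate correct inference on independent predictors, not
real-data prediction accuracy (absolute $R^2$ on real panels depends
strongly on LD).

`simulate_phenotype` implements four architectures on any panel:

* **I** — fully polygenic with four effect groups (defaults 10, 100, 1000
  and all remaining SNPs) explaining 0.05 / 0.15 / 0.20 / 0.60 of the
  genetic variance;
* **II** — sparse: the same three leading groups with shares
  0.1 / 0.2 / 0.7 and exactly zero effects elsewhere;
* **III** — two groups, `c_large` SNPs (10, 100 or 1000) versus the rest,
  shares 0.2 / 0.8;
* **IV** — one group, all SNPs causal, effects normal, t (4 df) or
  Laplace.

Raw effects are standard normal (scenarios I–III) or the scenario-IV
family, then each group block is rescaled so the *realized* variance of
its genetic contribution equals its target share exactly; noise is
residualized against the genetic values and the intercept before scaling,
so $\mathrm{var}(y) = \mathrm{var}(X\beta) + \mathrm{var}(\epsilon)$ holds
identically and the realized PVE equals the requested value to machine
precision. Rescaling by realized rather than expected variance is a
deliberate choice: it makes the study conditions exact and the tests
deterministic given a seed. t(4) effects are not variance-standardized
before rescaling (the rescaling absorbs the scale). Group assignment
samples SNPs without replacement; splits in the study driver are uniform
without stratification. Total PVE levels of 0.2 / 0.5 / 0.8 represent low,
moderate and high heritability; group sizes are overridable for panels too
small for the defaults.

## Evaluation

Prediction is the plug-in rule $\hat y = W\hat\alpha + X\hat\beta$ with
posterior-mean coefficients and training-mean centering. Accuracy is the
squared Pearson correlation (degenerate constant predictions score 0 with
a flag rather than NA) and mean squared error. `monte_carlo_cv` performs
seeded random 80/20 splits (20 by default). `compute_grm` forms
$X_s X_s^\top / p$ from standardized genotypes, and `effective_segments`
returns $M_e = 1/\mathrm{var}(\text{off-diagonal GRM})$, the effective
number of independent chromosome segments — small in related samples,
near the number of independent SNPs in unrelated ones. The $M_e$ formula
follows the standard literature definition; on simulated unrelated panels
the off-diagonal variance is approximately $1/p$, which the tests check.

## Univariate scale-mixture fitting

`fit_scale_mixture` runs the same Gibbs machinery on univariate samples
(the observations play the role of the effects; no design matrix), which
is how one demonstrates the prior's flexibility: on heavy-tailed t(4)
samples the fitted mixture's held-out log-likelihood beats the best
single-normal fit, and on a 0.8·t(4) + 0.2·δ₀ point-mass contamination it
allocates a component with variance below $10^{-3}$. The density evaluator
averages the mixture density over kept posterior draws (a posterior
predictive, Rao–Blackwellized over draws); reported components are sorted
by decreasing posterior-mean variance.

## Numerical choices and degenerate inputs

* Assignment sampling uses max-subtracted exponentials (MCMC) and
  log-sum-exp (VB); responsibilities are renormalized every update.
* Inverse-gamma draws guard against zero gamma variates at the smallest
  representable double.
* Sticks drawn at exactly 0 or 1 are nudged by $10^{-12}$; $\log(1-\nu)$
  is clamped at $-700$.
* Component variances initialize on an increasing grid scaled by
  $\mathrm{var}(y)/p$ to break symmetry; assignments initialize uniformly
  at random (MCMC) or uniformly in expectation (VB).
* Monomorphic (constant) SNP columns carry no likelihood information and
  their effects revert to the prior; fully missing SNPs are an error at
  imputation (they should have failed call-rate QC).
* Collinear covariates, missing values at fit time, empty QC panels,
  constant phenotypes in $R^2$, and rank-degenerate quantile normalization
  all raise informative errors rather than propagating NaNs; non-finite
  sampler states abort with the sweep index.
* All randomness flows through R's RNG (also inside the compiled sampler),
  so a single `seed` argument makes every fit, simulation and split
  reproducible.

## Problem sizes used by the tests

The test suite and the acceptance script run entirely on simulated data:
oracle checks on panels of up to 8 individuals and 2 SNPs ($10^5$ sweeps),
module tests on tens-to-hundreds of individuals, heritability recovery on
n = 1000, p = 500 with 3000 sweeps, and cross-validation studies on
n = 800, p = 300 with 1500 sweeps per fit. These sizes were chosen so the
full suite completes in a few minutes on one CPU while leaving every
statistical assertion comfortably powered; the algorithms themselves scale
linearly in n and p per sweep.

## Known limitations

* No LD-structured genotype simulation (coalescent or haplotype-based);
  conclusions about prediction accuracy on real, LD-rich panels cannot be
  drawn from the built-in simulator.
* VB accuracy degrades with heritability (posterior independence across
  SNPs); no structured VB is provided.
* Continuous phenotypes only — no generalized-linear extension for
  case-control or count data.
* The truncated blocked sampler is the only MCMC kernel; no slice or
  retrospective sampler for the untruncated process.
* A supplementary reference implementation may fix different hyper-prior
  values or marginalize $\beta_i$ when sampling assignments; our defaults
  are declared above and are not claimed to match any external software
  draw for draw.
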