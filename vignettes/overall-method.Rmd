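---
title: "Gene-based association testing with eQTL-derived weights: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-based association testing with eQTL-derived weights: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(overallgene)
```

## The statistical model

For a gene with $M$ variants, let $\mathbf{Z} = (Z_1,\dots,Z_M)^\top$ be the
per-variant association Z-scores from a GWAS (either published summary
statistics or computed from individual-level data by per-variant least
squares).  Under the null hypothesis that no variant in the gene is
associated with the trait,
$$\mathbf{Z} \sim \mathrm{MVN}(\mathbf{0}, \mathbf{R}),$$
where $\mathbf{R}$ is the correlation (LD) matrix of the variants.  When
$\mathbf{R}$ is estimated from a modest external reference panel it is
noisy, which inflates gene-based test statistics.  The package therefore
shrinks it toward the identity,
$$\mathbf{U} = a\,\mathbf{R} + (1-a)\,\mathbf{I}_M, \qquad 0 \le a \le 1,$$
with $\hat a$ the maximizer of the $\mathrm{MVN}(\mathbf{0},\mathbf{U})$
log-likelihood of the observed $\mathbf{Z}$ (`estimate_tuning()`).  The
likelihood profile is evaluated in the eigenbasis of $\mathbf{R}$, scanned
on a 21-point grid and refined by golden-section search to a tolerance of
$10^{-4}$ on $a$.  Two numerical conventions matter:

* flat profiles (e.g. $\mathbf{R} = \mathbf{I}$) are resolved toward
  $a = 1$, so a perfectly estimated LD matrix is never shrunk;
* a singular $\mathbf{R}$ at $a = 1$ is evaluated with a $10^{-10}$ ridge,
  for the likelihood only — the reported $\mathbf{U}$ is unridged.

## The weighted test battery

$K$ eQTL-derived weight vectors $\hat{\mathbf{W}}_k$ (per-variant effects on
the gene's expression, e.g. BLUP estimates from expression panels) are
standardized to remove their scale, $W^k_m = \hat W^k_m / \sum_m |\hat
W^k_m|$, and the unweighted vector of ones is included as $k = 0$.  For each
weight the package computes three tests of
$H_0: \mathbf{Z} \sim \mathrm{MVN}(\mathbf{0}, \hat{\mathbf{U}})$:

* burden: $Q_{BT} = (\mathbf{Z}^\top \mathbf{W}_k \mathbf{1})^2$, referred
  to $v\,\chi^2_1$ with $v = \mathbf{w}_k^\top \hat{\mathbf{U}}
  \mathbf{w}_k$ (the variance normalization that makes the 1-df reference
  exact);
* SKAT: $Q_{SKAT} = (\mathbf{W}_k\mathbf{Z})^\top \mathbf{W}_k\mathbf{Z}$,
  whose null is the weighted sum of 1-df chi-squares with weights the
  eigenvalues of $\hat{\boldsymbol\Sigma}_k = \mathbf{W}_k \hat{\mathbf{U}}
  \mathbf{W}_k$;
* SKAT-O: $\min_{\rho} \{(1-\rho) Q_{SKAT} + \rho\, Q_{BT}\}$ over the grid
  $\rho \in \{0, 0.1^2, \dots, 0.9^2, 1\}$ (the canonical grid; the choice
  is configurable).

This yields $L = 3(K+1)$ p-values per gene.

### Quadratic-form tail probabilities

The weighted chi-square survival function is the core numerical primitive
(`quad_form_pvalue()`), implemented in compiled code as characteristic-
function inversion of the Imhof type.  The oscillatory inversion integrand
is marched in sub-half-period Gauss–Legendre panels; with five or more
eigenvalues the envelope decays quickly and integration stops on a
per-oscillation tail bound, while few-eigenvalue (slowly decaying)
integrands switch to exact zero-crossing segmentation with iterated-mean
acceleration of the alternating series.  Additional numerical policy:

* eigenvalues below $10^{-10}$ of the largest are dropped before inversion;
  at relaxed accuracy, further negligible eigenvalues are absorbed into the
  quantile by their mean, with the (second-order) error kept far below the
  requested accuracy;
* deep tails, where inversion loses absolute precision, are screened by a
  cheap moment estimate and handed to a Lugannani–Rice saddlepoint, which
  is relatively accurate there;
* the Liu-type moment-matching approximation is the last-resort fallback
  (signalled with a message) and supplies starting values for quantile
  inversion;
* p-values are floored at $10^{-300}$ so downstream correlation and
  combination steps never see zeros.

The default absolute accuracy is $10^{-9}$; the closed-form special cases
(single eigenvalue, all eigenvalues equal) are exact.

### The SKAT-O null

Writing $\xi = \mathbf{1}^\top \mathbf{W}_k \mathbf{Z} / \sqrt{\psi}$ with
$\psi = \mathbf{1}^\top \boldsymbol\Sigma_k \mathbf{1}$ for the common
burden component, every $Q_\rho$ is $(1-\rho) S + \rho\,\psi\,\xi^2$, and
conditionally on $\xi$ the SKAT part $S$ is an *exact* noncentral weighted
chi-square (eigenvalues of $\boldsymbol\Sigma_k -
\boldsymbol\Sigma_k\mathbf{1}\mathbf{1}^\top\boldsymbol\Sigma_k/\psi$,
noncentralities proportional to $\xi^2$).  The SKAT-O p-value — the null
probability that the smallest per-$\rho$ p-value falls below the observed
minimum — is therefore a one-dimensional integral over $\xi$, evaluated
adaptively with per-$\rho$ null quantiles obtained by inverting the exact
survival function.  This avoids the moment-matching step of the widely used
variance-adjusted construction; the two agree closely in the bulk, and the
exact route is what the Monte-Carlo oracle tests validate.  Because the
exact route is relatively expensive, the replication loops (null-correlation
estimation and the simulation experiments) use the moment-matched
variant (`fast = TRUE`), whose error is negligible at the significance
levels those experiments measure.  The result is always bracketed by
$[\min_\rho p_\rho,\ |\text{grid}|\cdot \min_\rho p_\rho]$.

## Combining the battery: extended Simes

With $p_{(1)} \le \dots \le p_{(L)}$ the ordered p-values, the combined
gene-level p-value is
$$p_{\mathrm{overall}} = \min_{l} \frac{m_e\, p_{(l)}}{m_{e(l)}},
\qquad m_{e(l)} = l - \sum_{i=1}^{l} (\lambda_i - 1)\,
\mathbb{1}(\lambda_i > 1),$$
where the $\lambda_i$ are eigenvalues of the submatrix of the null p-value
correlation matrix $\boldsymbol\Omega$ corresponding to the $l$ smallest
p-values, and $m_e = m_{e(L)}$.  Independent tests give $m_{e(l)} = l$ (the
classical Simes procedure); perfectly dependent tests give $m_{e(l)} = 1$.
Conventions: "top $l$ tests" means the $l$ smallest p-values with ties
broken by the canonical label order; eigenvalues of estimated submatrices
are clipped at zero before the sum; the minimum is capped at 1.

$\boldsymbol\Omega$ is estimated once per gene by replication
(`estimate_null_correlation()`): draw $\mathbf{Z}^{\mathrm{null}} \sim
\mathrm{MVN}(\mathbf{0},\mathbf{R})$, re-apply the regularization (the
shrinkage parameter is re-estimated per replicate by default, with a flag
to freeze it), compute all $L$ p-values, and take the Pearson sample
correlation across $B$ replications of the p-value columns.  $B = 1000$ is
the default; `omega_convergence()` reports the maximum-entry and Frobenius
distances to a larger-$B$ reference so users can check that 1000 is enough
for their gene.

## Comparators

* OT (Cauchy combination): $p_{OT} = \tfrac12 - \arctan(Q_{OT})/\pi$ with
  $Q_{OT}$ the mean of $\tan\{(0.5 - p)\pi\}$ over all $L$ p-values; inputs
  are clipped into $[10^{-15}, 1 - 10^{-15}]$ to avoid infinite tangents.
* S-TWAS: $Z = \mathbf{w}^\top \mathbf{Z} / \sqrt{\mathbf{w}^\top
  \mathbf{R}\, \mathbf{w}}$, two-sided normal.
* S-PrediXcan: $Z = \sum_m W_m \hat\sigma_m Z_m / \hat\sigma$; with unit
  SNP standard deviations and $\hat\sigma$ computed from $\mathbf{R}$ it
  coincides with S-TWAS, which is how the simulations treat it.

The comparators use the raw $\mathbf{R}$, following their printed
definitions; `comparator_ld = "corrected"` substitutes $\hat{\mathbf{U}}$.

## The simulator and what it does (not) emulate

The simulation layer generates every input of the power study:

1. haplotype pools from a latent Gaussian AR(1) threshold model
   (`synth_haplotype_pool()`); the default pool (458 haplotypes, 23
   variants, latent correlation 0.7, roughly half common and half
   low-frequency variants) mimics the size and frequency mix of a small
   gene in a reference panel.  Individuals are sums of two haplotypes drawn
   with replacement; variants below a 5% MAF floor are removed;
2. sparse eQTL weights: per study, a causal subset of size
   $\max(1, \mathrm{round}(M\,p_{\mathrm{causal}}))$ with standard-normal
   raw effects, rescaled so the sample variance of the genetic score
   $\mathbf{X}\mathbf{w}_k$ equals the expression heritability $h_e^2$
   exactly; expression $\mathbf{E}_k = \mathbf{X}\mathbf{w}_k +
   \varepsilon$, $\varepsilon \sim N(0, 1-h_e^2)$.  Causal sets are drawn
   independently across studies;
3. phenotypes $\mathbf{Y} = \mathbf{E}\boldsymbol\beta + \varepsilon_p$,
   $\varepsilon_p \sim N(0, 1-h_p^2)$, with $\beta_0 = \sqrt{h_p^2/K}$ and
   scenarios: uni-directional ($\beta_k = \beta_0$), bi-directional (first
   half $+\beta_0$, second half $-\beta_0$), and, for $K = 4$, noisy
   variants in which the most relevant studies are perturbed by
   $N(0, 0.1 h_p^2)$ and the rest by $N(0, 0.5 h_p^2)$;
4. Z-scores by per-variant ordinary least squares with intercept.

The synthetic pool stands in for real reference-panel haplotypes: it
reproduces realistic MAF spectra and local LD decay but not the block
structure of any particular gene, so simulation results characterize the
methods' relative behaviour, not the absolute power attainable on a
specific locus.

### Experiment drivers and their design choices

`type1_experiment()` draws null Z-vectors directly from
$\mathrm{MVN}(\mathbf{0},\mathbf{R})$, estimates $\boldsymbol\Omega$ once,
and tabulates empirical rates.  In this experiment the generative truth is
$a = 1$ (the Z-scores come from the very matrix used as the null
covariance), and re-estimating $a$ from each single draw only injects
noise that visibly inflates even the exactly calibrated burden test when
the synthetic $\mathbf{R}$ is well-conditioned; with realistic
reference-panel LD, which is close to singular, the likelihood pins
$\hat a$ at 1 and refitting is innocuous.  The driver therefore fixes
$a = 1$ by default and exposes `refit_a = TRUE` for the general case.

`power_experiment()` redraws the full architecture — causal variants,
weights, expression, phenotype — with every replicate, analyses each
cohort with its own estimated LD (where the shrinkage refit is meaningful
and enabled), and reuses a per-cell $\boldsymbol\Omega$ estimated from the
pool LD and a representative weight draw, mirroring the
estimate-once-per-gene usage.  `BEST`, `S-TWAS.B` and `S-PrediXcan.B` are
reporting conventions (per-cell maxima over the component tests and
per-study comparators), not statistical tests.

Default experiment sizes (a 23-variant pool, $K = 4$, $B = 1000$
replications for $\boldsymbol\Omega$, $5\times10^4$ null replicates for
type-I rates, 200 cohorts per power cell at $n = 2000$) keep a full run on
a single core in the tens of minutes while leaving binomial standard
errors small relative to the effects of interest; all drivers accept
larger values.

## Known limitations

* The extended-Simes and Cauchy combinations have approximate nulls; their
  empirical type-I error is near-nominal at conventional levels but can
  drift by factors of ~2 at genome-wide tail levels, as is visible in any
  deep-tail calibration of such combinations.
* $\boldsymbol\Omega$ is a correlation of p-values estimated from $B$
  replications; genes with highly degenerate weights can produce constant
  p-value columns, which are assigned zero correlation with a warning.
* The moment-matched SKAT-O route trades a small (order $10^{-3}$
  relative, bulk) approximation error for a ~50-fold speedup; single-gene
  analyses use the exact route by default.
* Binary (case-control) phenotypes, covariate adjustment, MAF-based
  rare-variant weighting and multi-tissue extensions are out of scope.
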