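---
title: "Spike-and-slab variational whole-genome regression: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spike-and-slab variational whole-genome regression: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

slabgwas performs mixed-model association testing in two steps. Step one
fits a Bayesian whole-genome regression with a spike-and-slab prior on
variant effects and turns it into leave-one-chromosome-out (LOCO) residual
phenotypes; step two scans variants with proportional score statistics,
calibrated so that their scale matches an effective sample size, with an
approximate Firth fallback for unstable binary tests. This vignette
explains the models, the numerical machinery, the choices that were
genuinely open, and what the synthetic-data experiments do and do not show.

## The step-1 model

For a covariate-adjusted, standardized genotype matrix $X$ ($N \times M$)
and adjusted phenotype $y$, the quantitative model is

$$ y \mid X, \beta \sim \mathcal N(X\beta, \sigma_e^2 I), \qquad
   \beta_j \sim (1 - p_1)\,\delta_0 + p_1\, \mathcal N(0, \sigma^2), $$

with $p_1$ the prior probability that a variant carries a nonzero effect
(the "slab"). Binary traits replace the likelihood with a Bernoulli
likelihood through the logistic link; covariate effects are estimated once
by a covariates-only logistic regression and enter the fit as a fixed
offset. The approximate posterior is fully factorized, each factor again
spike-and-slab with per-variant slab probability $\psi_j$, slab mean
$\mu_j$ and slab variance $\sigma_j^2$.

The evidence lower bound (ELBO) is the expected log likelihood minus a KL
penalty which separates per variant into a Bernoulli part and a
slab-weighted Gaussian part:

$$ \mathrm{KL}_j = \mathrm{KL}\!\left(\mathrm{Bern}(\psi_j)\,\|\,
   \mathrm{Bern}(p_1)\right) + \psi_j \cdot \tfrac12\!\left(-1 +
   \tfrac{\mu_j^2 + \sigma_j^2}{\sigma^2} -
   \log\tfrac{\sigma_j^2}{\sigma^2}\right). $$

We store the slab probability (the probability of a *nonzero* effect) and
weight the Gaussian KL by it; this makes the penalty exactly the KL
divergence between the two mixtures, which the test suite verifies by
Monte-Carlo integration. The linear-model ELBO includes the Gaussian
normalizing constant, so its full-data value is a true lower bound on the
log evidence — the acceptance tests check this against exhaustive
enumeration of all spike/slab configurations at $M = 8$.

### Stochastic optimization

The ELBO is maximized by minibatch Adam on unconstrained
reparameterizations: $\mathrm{logit}\,\psi_j$, $\mu_j$ and
$\log\sigma_j^2$. Two variance-reduction devices keep the stochastic
gradient usable at one Monte-Carlo sample per batch:

* **Local reparameterization.** Instead of sampling $\beta$, each
  sample's linear predictor is drawn from its implied Gaussian with mean
  $\sum_j x_{ij}\psi_j\mu_j$ and variance $\sum_j x_{ij}^2\,[\psi_j
  (\sigma_j^2 + \mu_j^2) - \psi_j^2\mu_j^2]$.
* **Antithetic variates.** Each draw is used as a $\pm z$ pair. For the
  linear model the paired mean-gradient noise cancels exactly, so the
  default of one pair per batch already gives low-variance updates.

Defaults: step size 0.01, batch size 128, at most 100 epochs, convergence
when the smoothed (window 5) full-data ELBO changes by less than $10^{-4}$
relative over 5 epochs. All are configurable through `svi_control()`; the
larger desk-scale experiments in the test suite use batch 256 and evaluate
the convergence trace every other epoch, which changes only the stopping
schedule, not the objective. With a fixed seed the fit is bit-reproducible.

### Prior from variance components

For a standardized trait, $M\,p_1\,\sigma^2 = h^2$ ties the slab variance
to the heritability, and $\sigma_e^2 = 1 - h^2$. Quantitative $h^2$ comes
from single-component randomized Haseman–Elston regression: the
method-of-moments system in $\mathrm{tr}(K)$ (exact) and
$\mathrm{tr}(K^2)$ (Hutchinson estimator with 50 Rademacher vectors,
default), never forming the GRM; all traits share the trace estimates.
Negative estimates are clamped at zero, and the heritability entering the
prior is clamped to $[0.01, 0.95]$ to keep it proper. Binary $h^2$ comes
from a grid search over $\{0.01, 0.25, 0.5, 0.75\}$, refitting the
logistic regression at each value. The selection criterion is the
converged full-data ELBO: "highest likelihood" admits several readings
(training pseudo-likelihood, held-out likelihood), and the ELBO is the
quantity the optimizer itself maximizes, needs no extra data split, and
recovered the truth-adjacent grid point in liability simulations. The
prior slab probability defaults to 0.01; it can be set per run.

### LOCO residuals and transfer learning

One whole-genome fit is run first (with a 10% held-out sample split when
`holdout_frac` is set); each per-chromosome fit then drops that
chromosome's columns and warm-starts every remaining parameter from the
whole-genome posterior. Warm-started fits reach the cold-start ELBO in a
quarter or less of the epochs in the test suite's transfer experiment.
The LOCO residual for chromosome $c$ is $\tilde y_c = y - X_{-c}
E[\beta_{-c}]$ (quantitative) or the null prediction $\hat p_c =
\mathrm{sigmoid}(\text{offset} + X_{-c} E[\beta_{-c}])$ (binary). The
held-out residual-variance ratio $\mathrm{var}(y)/\mathrm{var}(y -
X\hat\beta)$ on the held-out samples estimates the effective-sample-size
gain of conditioning on the polygenic predictor.

## Step-2 testing and calibration

The proportional statistics are
$\chi^2_Q \propto (x^\top \tilde y_{\mathrm{LOCO}})^2 / (x^\top x)$ for
quantitative traits and
$T_B \propto x^\top(y - \hat p) / \sqrt{x^\top \hat W x}$,
$\hat W = \mathrm{diag}\{\hat p(1 - \hat p)\}$, for binary traits. The
constant of proportionality is fixed per trait by matching a mean-$\chi^2$
effective sample size:

$$ \gamma = \frac{(\bar\chi^2_{\mathrm{ref}} - 1)\cdot
  \underbrace{\mathrm{var}(y)/\mathrm{var}(\tilde y)}_{\text{held-out gain}}
  \cdot \underbrace{N_{\mathrm{eff}}/N_{\mathrm{ref}}}_{\text{relatedness}}
  + 1}{\bar\chi^2_{\mathrm{raw}}}, $$

where $\bar\chi^2_{\mathrm{ref}}$ is the mean statistic of plain linear or
logistic regression with covariates on an unrelated homogeneous subset,
evaluated on a random calibration set of 5% of the tested variants (at
least 1,000), and $\bar\chi^2_{\mathrm{raw}}$ is the mean raw statistic of
the same variants on the full sample. $N_{\mathrm{eff}} = N - \sum 2\phi$
discounts detected relative pairs; kinship comes from a
standardized-genotype estimator on up to 5,000 markers, with the detection
floor raised from the third-degree threshold $2^{-4.5}$ to five noise
standard deviations $5/(2\sqrt{M})$ when few markers are available — with
a small panel the estimator cannot distinguish third-degree relatives
from noise, and flooding the pair list would destroy the calibration
subset. The exact functional form combining the held-out gain and the
relatedness discount is this package's documented reconstruction; only
its ingredients are fixed by the method's description. P-values are
computed in log space, and the reported score-test standard error is
derived as $|\hat\beta|/\sqrt{\chi^2_{\mathrm{cal}}}$ so that effect, SE
and p-value are mutually consistent.

Binary statistics below $p = 0.05$ at rare variants (MAF < 5%) or for rare
traits (prevalence < 5%) are re-tested with an approximate Firth
penalized-likelihood ratio test: covariate and LOCO-offset effects are
fixed at their null fit, and the single variant parameter maximizes
$\ell(\beta) + \tfrac12\log I(\beta)$ by damped Newton. The Jeffreys
penalty guarantees a finite estimate under separation. The approximation
is accurate because the tested dosage is centered (covariate-adjusted),
hence near-orthogonal to the fixed null terms; the tests compare against
brute-force grid maximization and a both-parameters-penalized reference
fit. No saddle-point approximation is implemented.

Optional participation weights turn the quantitative scan into weighted
least squares with a Huber–White variance,
$\widehat{\mathrm{Var}}(\hat\beta) = (x^\top W x)^{-2} \sum_i w_i^2 x_i^2
r_i^2$, recalibrated against a weighted reference regression. Note that
under this (sandwich-standard) convention, splitting a sample into
duplicates with half weight preserves the estimate but not the standard
error; inverse-probability analyses should center variables with weighted
means, as the bias-correction test does.

## The synthetic-data generator

The generator exists so every stage can be verified without any external
data. Its defaults are the documented study conditions: narrow-sense
heritability $h_g^2 = 0.4$; per-variant effect variance proportional to
$(2f(1-f))^{-0.3}$ on standardized dosages; 1% of variants causal for the
spike-and-slab architecture (all variants for Laplace/Gaussian), causal
variants restricted to odd chromosomes so even chromosomes are exact
nulls for false-positive measurement; stratification worth 5% of trait
variance when several populations are simulated; shared environment worth
20% / 10% of variance in first- / second-degree relatives; binary traits
by thresholding the liability at the empirical prevalence quantile, which
fixes the case count exactly (an $N = 50{,}000$, 30% prevalence
configuration yields exactly 15,000 cases). Ties in the liability are
broken by sample order; a constant liability is an error.

Genotypes are unlinked biallelic variants: founder MAFs are drawn
log-uniformly (density $\propto 1/f$, a neutral-spectrum-like choice) down
to a floor of $10^{-4}$, population frequencies follow a Balding–Nichols
Beta drift with parameter $F_{ST}$, unrelated individuals are
Hardy–Weinberg draws, and relative pairs are gene-dropped from simulated
parental haplotypes (full sibs for first degree, half sibs for second).
The stratification term is a fixed per-population offset drawn once and
rescaled to its variance share — the generative description fixes only
the variance, not the per-population draw law. Each realized trait
component is rescaled to its exact variance share, so the recorded
decomposition is exact rather than expected, and recovery tests compare
against realized truth.

What the generator does **not** emulate: linkage disequilibrium and
recombination maps, imputation noise, haplotype structure, sex
chromosomes, multi-allelic variants. Consequences worth keeping in mind:
without LD, proximal contamination is weaker than in real data, so the
LOCO scheme is exercised but not stress-tested; single-component
Haseman–Elston is unbiased here even under MAF-dependent architectures
(cross-variant correlations vanish), which would not hold under LD — the
multi-bin decomposition the method's full-scale version uses is out of
scope, with a MAF-binning hook left in `rhe_estimate()`.

## Problem sizes and what the experiments show

The verification experiments run at desk scale: the type-I-error study
uses $N = 2{,}000$ samples and $M = 20{,}000$ generated variants (about
9,000 pass the MAF $\ge 1\%$ QC, leaving roughly 4,600 even-chromosome
nulls) with 10 quantitative and 5 binary traits; heritability recovery
uses $N = 2{,}000$, $M = 5{,}000$ and 25 replicate traits; the
exact-posterior oracle uses $N = 60$, $M = 8$ where enumeration over all
$2^8$ configurations is feasible. These sizes were chosen so each
property is measured with useful precision while the full suite stays
comfortably runnable on a laptop. False-positive rates are judged against
the 95% binomial confidence interval for a single trait's null-variant
count, with per-trait rates averaged across traits; power comparisons use
the normalized causal statistic (mean causal $\chi^2$ over mean null
$\chi^2$) so that calibration differences cancel.

Observed at these scales: calibrated false-positive rates sit on the
nominal 0.05 and $10^{-3}$ lines for both trait types; the spike-and-slab
pipeline's normalized causal statistic exceeds plain regression under
sparse architectures and matches a dense Gaussian-prior pipeline under
infinitesimal architectures; randomized Haseman–Elston is centered on the
simulated $h^2 = 0.4$ and converges to the exact-trace solve as the
random-vector count grows.

## Numerical details and degenerate inputs

* Missing genotypes are mean-imputed before standardization; the default
  scale is the observed (population) standard deviation, with
  $\sqrt{2f(1-f)}$ as an option. Monomorphic and all-missing variants are
  excluded and logged.
* Slab probabilities are clamped to $[10^{-6}, 1 - 10^{-6}]$ and log slab
  variances to $[-30, 30]$; the implied predictor variance is floored at
  $10^{-12}$ before square roots.
* A non-finite ELBO twice in a row aborts the fit with advice to lower
  the step size; hitting `max_epochs` returns `converged = FALSE` rather
  than erroring.
* Zero-variance test dosages are skipped and logged, so every variant read
  is either tested or accounted for.
* A single-chromosome genome makes the LOCO complement empty; the
  residual is then the adjusted phenotype itself.
* Firth refits that cannot improve on the null return $\beta = 0$ with
  the score p-value retained and a flag.

## Known limitations

The two-bit-packed in-memory genotype store is not implemented; dosages
are held as one integer per genotype (the packed encoding exists in the
PLINK codec, where it is semantically identical). Multi-trait fitting
shares genotype passes but not information across traits — no correlated
priors. Step-1 and step-2 variant sets may differ in principle, but both
are read from PLINK hard calls; dosage formats (BGEN/VCF) are out of
scope. The cross-ancestry correlated-effect sampler is provided only as a
configuration hook and is off by default.
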