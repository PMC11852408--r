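---
title: "Methods: Bayesian meta-analysis of process variances"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian meta-analysis of process variances}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In biopharmaceutical platform processes, the variability of a critical
quality attribute (CQA) must be characterized for every product, but early
in development each product contributes only a handful of large-scale
batches. Classical per-product variance estimates are then extremely noisy.
Because products on a shared platform are manufactured similarly, their
variances are related, and a meta-analysis across products can stabilize
the estimates and — more importantly — predict the variance of a *future*
product before its own data exist.

`varmeta` implements a hierarchical random-variance (location–scale) model
for this purpose: the total standard deviation of each product is itself a
random effect drawn from a lognormal population.

## The model

For products $i = 1, \dots, n_P$:

$$\ln(\sigma_i) \sim N(\mu, \sigma)$$

**Single-cycle products** (one measurement per batch $j$):
$$y_{ij} \sim N(\mu_i, \sigma_i)$$

**Multi-cycle products** (cycles $k$ nested in batches $j$) split the total
variance into a between-batch component $\tau_i^2$ and a within-batch
(residual) component $\nu_i^2$:
$$\mu_{ij} \sim N(\mu_i, \tau_i), \qquad
  y_{ijk} \sim N(\mu_{ij}, \nu_i), \qquad
  \sigma_i^2 = \tau_i^2 + \nu_i^2.$$

Both kinds of products may coexist in one dataset; they share the same
population distribution, so the meta-analysis integrates them seamlessly.
The product means $\mu_i$ and the split $(\tau_i, \nu_i)$ are fixed
effects: only the *total* variance is modeled as random, and the two
components are treated as uncorrelated.

The quantity of applied interest is the posterior predictive distribution
of a future product's total SD,
$$p(S \mid Y) = \int p(S \mid \mu, \sigma)\, p(\mu, \sigma \mid Y)\,
  d(\mu, \sigma),$$
sampled as $S_d = \exp(\mu_d + \sigma_d z_d)$ over the retained posterior
draws. Its equal-tailed 95% interval is the prediction interval (PI) used,
for example, as a meta-analytic reference for expected process variance.

## Priors, parameterization, and design choices

Several details are deliberate package choices where the modeling
literature leaves latitude; they are recorded here.

* **Priors.** Weakly informative standard-normal priors on the population
  parameters: $\mu \sim N(0, s_\mu)$ and a *half*-normal
  $\sigma \sim N^+(0, s_\sigma)$, defaults $s_\mu = s_\sigma = 1$. A plain
  normal prior is not a density on a scale parameter, so the positive
  truncation is the natural reading; it is also standard practice for
  hierarchical scales. The product means get $\mu_i \sim N(0, 5)$ — wide
  relative to data simulated around zero. For real data, center the
  measurements (per product if need be) before fitting, or widen
  `product_mean_prior_sd`.
* **Variance split.** Each multi-cycle product is parameterized by
  $(\sigma_i, p_i)$ with $\tau_i^2 = p_i \sigma_i^2$,
  $\nu_i^2 = (1 - p_i)\sigma_i^2$ and $p_i \sim \mathrm{Uniform}(0, 1)$.
  This enforces $\sigma_i^2 = \tau_i^2 + \nu_i^2$ by construction and lets
  the lognormal population act on $\sigma_i$ identically in both model
  variants. The sampler works on $\mathrm{logit}(p_i)$, so the boundaries
  $p_i \in \{0, 1\}$ (a vanishing component) are excluded from the
  interior and never produce infinite densities.
* **Unconstrained sampling scale.** $\sigma$ and $\sigma_i$ are sampled on
  the log scale. Batch means are non-centered
  ($\mu_{ij} = \mu_i + \tau_i z_{ij}$), and the product log-SDs are
  non-centered as well: $\ln \sigma_i = \mu + \sigma u_i$ with
  $u_i \sim N(0,1)$. The latter matters: with few products and few batches
  the joint posterior of $(\sigma, \ln \sigma_i)$ forms a funnel, and the
  centered form showed divergent transitions and split-$\hat R$ failures
  in roughly 8% of replicates at the smallest design cell ($n_P = 5$,
  $n_b = 3$); the non-centered form eliminated them. The two forms target
  the same distribution — the package's tests verify the compiled density
  against the R reference assembly term by term.
* **Interval convention.** All credible and prediction intervals are
  equal-tailed quantile intervals, matching the percentile convention of
  the bootstrap uncertainty intervals.
* **Single-batch products** are permitted (their $\sigma_i$ is then
  informed almost entirely by the population — that is what partial
  pooling is for) but raise a warning so the user is aware.

## The sampler

No probabilistic-programming backend is required: the package bundles a
no-U-turn sampler (NUTS) written in C++ — the slice-sampling variant with
dual-averaging step-size adaptation and a windowed diagonal mass-matrix
estimate, i.e. the standard adaptive-HMC recipe. Defaults follow the
reference analysis: 2 chains × 5000 iterations including 1000 warmup,
thinning 2 (4000 retained draws), target acceptance 0.95, initial step size
0.05 (the step size then adapts; a fixed step size would contradict NUTS
adaptation), maximum tree depth 15.

Likelihood and gradient evaluations use per-batch sufficient statistics
$(n, \sum y, \sum y^2)$, so one gradient costs $O(n_P + \text{batches})$
regardless of the number of measurements — this is what makes
simulation studies with hundreds of full Bayesian fits feasible on one CPU.

Convergence diagnostics are computed by the package itself (not the
sampler): split-$\hat R$ (each chain halved before the between/within
comparison — more conservative than the original Gelman–Rubin statistic)
and autocorrelation-based effective sample size with Geyer's initial
monotone positive-sequence truncation. A fit warns when any parameter has
split-$\hat R > 1.05$ or when post-warmup divergences occurred.

## What the synthetic-data generator emulates

`simulate_dataset()` reproduces the generative process of the model with
the reference population $(\mu, \sigma) = (0.1, 0.4)$ — values chosen in
the source analysis to match the realistic magnitude of historical process
variability — product means fixed at zero, and (for multi-cycle designs) a
single $\tau_i/\nu_i$ ratio applied to all products of a dataset. The
generator is the model: a green simulation study therefore establishes
*self-consistency* (correct inference when the model is true), not
robustness to model misspecification. Real CQA data bring non-lognormal
variance populations, outlier products of dissimilar molecule type,
correlated variance components and time trends — none of which the
generator produces; a real-data meta-analysis should precede model fitting
with the QQ-plausibility check (`qq_lognormal()`) and a similarity
pre-assessment of the products.

Seeding is counter-based: `child_seed(root, rep, stream)` derives
independent, order-free seeds per replicate and purpose (0 = data,
1 = sampler, 2 = predictive draws), so any single replicate of a study can
be regenerated in isolation.

## The simulation-study harness

`run_scenario()` repeats generate–fit–evaluate `n_sim` times and records,
per replicate, the posterior means and 95% CIs of $\mu$ and $\sigma$, the
95% PI of $S$, and whether a freshly drawn future-product SD
$\sigma_{new} \sim \mathrm{LogNormal}(\mu_{true}, \sigma_{true})$ falls in
the PI — the standard predictive-coverage construction. Aggregates (mean
estimates, empirical SEs, CI/PI coverages) carry non-parametric bootstrap
95% percentile intervals (default 10,000 resamples). Replicates flagged
non-convergent (any split-$\hat R > 1.05$) are excluded from aggregates
and counted, never re-run — re-drawing seeds until convergence would bias
the study. The fitting backend is injectable; the test suite exploits this
with an exact-posterior conjugate stub whose CI coverage is exactly
nominal, validating the harness independently of the sampler.

`run_study()` iterates scenarios over a grid. The full reference grid
($n_P \in \{5,7,10,15,25,50\} \times n_b \in \{3,5,7,10,15,25,50\}$,
$n_{sim} = 1000$) is cluster-scale; the `"desk"` preset
($\{5,15,50\} \times \{3,10,50\}$, $n_{sim} = 200$) runs on a laptop. The
package's acceptance checks run individual desk-scale cells
($n_{sim} = 100$–$200$) with full default MCMC settings per fit.

At desk scale the harness reproduces the qualitative findings of the
reference analysis: $\hat\mu$ recovers $\mu$ for moderate sample sizes
while $\hat\sigma$ overestimates $\sigma$ at small $n_P, n_b$; CI and PI
coverages sit at or slightly above 95%, with the PI coverage of the
multi-cycle configuration consistent with nominal. (No number is quoted
here that the test suite and `scripts/acceptance.R` do not themselves
compute.)

## Numerical notes

* `exp(log_random_effect)` integrates to 1 over $\sigma_i$ (quadrature
  tolerance 1e-6); $\sigma_i^2 = \tau_i^2 + \nu_i^2$ is enforced to
  relative 1e-10 by every constructor.
* The degenerate population $\sigma = 0$ is accepted by the simulator
  (every $\sigma_i = e^\mu$ exactly) but rejected by the density
  functions, which require $\sigma > 0$.
* The QQ table fits location/scale by least squares of the ordered
  log-SDs on the normal plotting-position quantiles, so input lying
  exactly on lognormal quantiles reproduces the generating parameters and
  falls on the identity line to machine precision; the moment estimator
  (mean/SD) would not.
* Bootstrap, predictive and new-product draws inside the harness use
  dedicated seed streams; identical configuration implies bit-identical
  results, including the per-replicate record file.

## Known limitations

* Only lognormal variance populations; no correlated $(\tau_i, \nu_i)$
  structures; no random effects on the individual components — all
  deliberate scope boundaries of the model.
* The sampler is single-threaded; the full 42-cell × 1000-replicate study
  is feasible but slow (hours), intended for scheduled runs rather than
  interactive use.
* Formal goodness-of-fit testing of the lognormality assumption
  (Kolmogorov–Smirnov, Anderson–Darling) is left to the user; the package
  provides the QQ table as the plausibility check.
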