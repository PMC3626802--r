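---
title: "Propagating probe-level measurement error through expression analysis"
author: "uexpress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Propagating probe-level measurement error through expression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uexpress)
```

Microarray expression estimates are not point measurements: the probes that
interrogate a target differ in affinity, targets share probes with other
isoforms, and weakly expressed genes sit close to the background. `uexpress`
treats every expression value as a Gaussian *(mean, sd)* pair on the log2
scale and carries that uncertainty from probe-level summarisation into
differential-expression scoring and clustering. This vignette explains the
four models, the choices behind their defaults, and what the simulation-based
tests do and do not establish.

## The compound-gamma summarisation models

Both summarisation methods rest on one distributional building block. A
probe's intensity is gamma-distributed given a probe-specific rate, and that
rate — the *probe effect*, the sequence-dependent affinity of a 25-mer —
carries its own gamma distribution:

$$ y \mid \beta \sim \mathrm{Ga}(a, \beta), \qquad \beta \sim \mathrm{Ga}(c, d), $$

with all gammas parameterised by shape and *rate*. The rate convention is
forced by the model structure: independent gamma variables add into a gamma
only when they share a rate, and the multi-mapping model (below) relies on
that closure. Integrating the probe effect out gives the closed form
implemented by `compound_gamma_logpdf()`:

$$ p(y) = \frac{\Gamma(a+c)}{\Gamma(a)\,\Gamma(c)}\,
   \frac{d^{\,c}\, y^{\,a-1}}{(y+d)^{\,a+c}}, $$

a heavy-tailed density whose tail index is the prior shape $c$. The unit
tests verify this expression against adaptive quadrature of the defining
integral at $10^{-8}$ relative accuracy.

### Multi-mapped exon probes

On exon arrays a probe $j$ of gene $g$ may lie in an exon shared by several
isoforms. Its intensity is modelled as the sum of gamma contributions of the
isoforms in its mapping set $M(g,j)$, each with its own shape
$\alpha_{kc}$ per array $c$ but sharing the probe effect $\beta_j$, so
$y_{jc} \sim \mathrm{Ga}\bigl(\sum_{k \in M(g,j)} \alpha_{kc},\, \beta_j\bigr)$.
The marginal likelihood of a gene factorises over (probe, array) pairs,
one analytic integral each. `fit_gme_gene()` maximises this objective plus a
weak Gaussian penalty (sd 3) on all log parameters; optimisation runs in log
space (positivity for free) with analytic gradients, three multistarts from
a perturbed method-of-moments initialisation, and box bounds
$|\log\theta| \le 10$ that keep the optimiser out of a spurious ridge
($\alpha \to \infty$, $d \to 0$) the factorised likelihood exhibits on
degenerate data. Fits that touch a bound are flagged, never silently kept.

Expression summaries come from the exact moments of the compound
distribution: if $s \mid \beta \sim \mathrm{Ga}(\alpha, \beta)$ and
$\beta \sim \mathrm{Ga}(c, d)$ then

$$ \mathbb{E}[\log s] = \psi(\alpha) - \psi(c) + \log d, \qquad
   \mathrm{Var}[\log s] = \psi'(\alpha) + \psi'(c), $$

with $\psi$, $\psi'$ the digamma and trigamma functions; both are divided by
$\log 2$ for the log2-scale output. Because a sum of same-rate gammas is
gamma with the summed shape, the gene-level summary is the same formula at
$\sum_k \alpha_{kc}$. No sampling, no Laplace expansion: the Gaussian
approximation sits on exact moments, and after the probe effect is
integrated over its fitted distribution the summary no longer depends on
the probe index, so one value per (target, array) is reported.

Two identifiability facts matter in practice. First, a probe shared by
several isoforms informs only the *sum* of their shapes; the split is
resolved by probes unique to each isoform, and `fit_gme_gene()` flags genes
whose probe-to-isoform incidence matrix is rank-deficient. Second, the
factorised likelihood leaves a nearly flat trade-off between $\alpha$ and
$(c,d)$ at small probe counts: with 8 probes and 4 arrays the median
relative error on recovered shape sums is roughly 40% in our simulations,
dropping as probes and arrays grow. The expression summaries, which combine
the three parameters, are estimated better than the raw shapes. Users
should treat per-isoform shape estimates from few probes as noisy and rely
on the reported uncertainty.

### PM-only probe-sets

For 3' GeneChips the same model with a single "isoform" per probe-set gives
the PM-only summarisation: $y_{jc} \sim \mathrm{Ga}(\alpha_c, b_j)$,
$b_j \sim \mathrm{Ga}(c, d)$. Discarding mismatch probes avoids the
instability of PM−MM differencing for weak signals, where background
exceeds signal and log-scale estimates blow up. `fit_pm_mmgmos()` delegates
to the same optimiser, so the equality between a PM-only fit and a
single-isoform gene fit is exact at the parameter level — a structural
identity the test suite asserts at $10^{-8}$. Since the trigamma function
is decreasing, small fitted shapes (weak expression) automatically yield
large reported sds: weakly expressed targets are summarised as uncertain
rather than wrong, which is precisely what downstream methods need.

### Normalisation

`global_scaling_normalize()` equalises a per-array location statistic (raw
mean, raw median, or mean of logs) across arrays. The common target is the
across-array average of that statistic, which makes the operation symmetric
in the arrays and idempotent. On expression results the scaling becomes an
additive shift of the log2 means and the sds are untouched — a location
shift does not alter spread. Both the probe-intensity and the
expression-result entry points are exposed; which to use depends on whether
normalisation should precede or follow summarisation, and applying either
twice is harmless.

## Differential expression with an analytic E-step

Per gene, measured log2 values $\hat x_{ij}$ (replicate $i$, condition $j$)
carry known measurement variances $s_{ij}^2$ from summarisation. The
hierarchy is

$$ \hat x_{ij} \sim N(x_{ij}, s_{ij}^2), \quad
   x_{ij} \sim N(\mu_j, \lambda^{-1}), \quad
   \mu_j \sim N(\mu_0, \eta_0^{-1}), \quad
   \lambda \sim \mathrm{Ga}(\alpha, \beta), $$

with the between-replicate precision $\lambda$ shared across conditions
within a gene but not across genes. The explicit latent layer $x_{ij}$ is
what makes inference fully conjugate: the factorised posterior
$q(x)\,q(\mu)\,q(\lambda)$ has Gaussian, Gaussian and Gamma coordinate
updates in closed form, so the E-step needs no importance sampling, and the
evidence lower bound increases monotonically (asserted on every run in the
tests). Convergence is declared at a relative ELBO change of $10^{-6}$,
capped at 500 iterations.

Hyperparameters $(\mu_0, \eta_0, \alpha, \beta)$ are shared across genes
and fitted by maximum likelihood inside the same EM (empirical Bayes); the
noninformative-hyperprior treatment is realised as ML point estimation and
`combine_replicates_ipplr()` also accepts fixed values. The
probability of positive log-ratio between treatment $t$ and control $c$ is
$\mathrm{PPLR} = \Phi\!\bigl((m_t - m_c)/\sqrt{v_t + v_c}\bigr)$ under the
variational posteriors, with up-regulation read from $\mathrm{PPLR} > 0.5$,
and genes ranked by $\max(\mathrm{PPLR}, 1-\mathrm{PPLR})$. No
multiple-testing adjustment is applied: the ranking itself is the result.

For validation the package ships `pplr_importance_sampling_oracle()`, a
reference implementation of the sampling-based computation it replaces:
$\lambda$ is drawn from a conjugate Gamma proposal, each condition's
likelihood given $\lambda$ is evaluated analytically with the condition
mean integrated out (a rank-one Sherman–Morrison update), and PPLR is the
self-normalised weighted average of per-sample normal CDFs, with an
effective-sample-size guard. On simulated data the analytic solver and the
reference at 10,000 samples agree to a mean absolute difference below 0.02.
The residual gap is a known property of mean-field inference: factorising
$q(x)\,q(\mu)$ drops their posterior correlation, which slightly inflates
the expected squared deviations and hence underestimates $\lambda$; the
effect grows with the ratio of measurement to replicate variance. For the
same reason empirical-Bayes estimates of the $\lambda$ prior mean are
biased low when measurement noise dominates — a limitation users should
know when interpreting the fitted hyperparameters (the PPLR ranking is much
less affected, as the bias is shared across genes).

## Robust clustering of replicated profiles

`fit_tmixture()` clusters genes by their latent condition-mean profiles
$w_n$ while modelling two further layers: known per-value measurement
variance ($x_{nji} \sim N(t_{nji}, s_{nji})$) and gene-specific replicate
variability ($t_{nji} \sim N(w_{nj}, 1/\eta_n)$, with $\eta_n$ shared
across conditions and given a per-component Gamma prior). The profiles
follow a mixture of Student's-$t$ distributions, written as Gaussians whose
precisions are scaled by Gamma latents $u_n$ — the heavy tails that let
outlying genes be absorbed instead of dragging centres. All E-step updates
are closed-form (Gaussian for $t$ and $w$, Gamma for $\eta$ and $u$,
multinomial for assignments); the M-step is closed-form except the degrees
of freedom, found by one-dimensional search on $[0.1, 200]$, and the
variational free energy is monotone (asserted in tests). Component
covariances are diagonal: profiles are short vectors and full covariances
destabilise model selection at realistic gene counts; an option could lift
this, but it is deliberately not the default.

Three numerical choices deserve a note:

* **Variance floor.** Component variances are kept above 5% of the
  per-dimension variance of the profiles (`min_var_frac`). Without it, a
  component can collapse onto a handful of near-identical genes, the
  likelihood diverges, and model selection favours spurious tiny clusters —
  the classical mixture singularity.
* **Robust seeding.** Initial centres come from k-means++ run on
  profiles winsorised at the 2% quantiles. Plain k-means++ prefers far
  points and therefore seeds on exactly the outliers the $t$-mixture is
  meant to resist; with winsorised seeding the fit starts in the bulk and
  the heavy tails do their job (the fitted dof drop below 5 when scattered
  outliers are present, and centres move by less than half a unit where a
  Gaussian mixture's move by many).
* **Gaussian limit.** With `fix_nu` and `fix_eta` large and negligible
  measurement variance the model reduces exactly to a diagonal Gaussian
  mixture; the tests verify centre agreement with an independent EM to
  $10^{-4}$. The in-package `fit_gaussian_mixture()` exists as that
  non-robust control and is itself cross-checked against mclust.

The number of components is chosen by minimum message length:
`select_k_mml()` starts at `maxcls`, applies the support-based weight rule
(components with fewer than $N_p/2$ effective observations are annihilated
during EM, never below `mincls`), then repeatedly removes the weakest
surviving component down to `mincls`, scoring every visited model with

$$ \mathrm{ML} = -\mathcal{F} + \frac{N_p}{2} \sum_{k:\Pi_k>0}
   \log\frac{n\Pi_k}{12} + \frac{K_{nz}}{2}\log\frac{n}{12} +
   \frac{K_{nz}(N_p+1)}{2}, $$

where $N_p = 2J+3$ counts each component's free parameters and the
variational free energy $\mathcal{F}$ stands in for the observed-data
log-likelihood, which the latent layers make intractable. On simulated
three-cluster data (centre separation about 10 profile sds, 300 genes) the
planted $K$ is selected in 19–20 of 20 seeds, and a single Gaussian blob
yields $K=1$ in 20 of 20.

## What the generators emulate — and what they do not

The `simulate_*` functions draw from exactly the models above with known
ground truth, so every pipeline stage is testable offline. Defaults are
frozen at values a microarray analyst would call realistic: log2 expression
means around 7, measurement sds from 0.05 up to about 1 (largest for weak
signals), two to three replicates per condition, gamma probe-effect priors
with shape 2–8 (probe affinities varying by severalfold), per-isoform
shapes 2–30. One deliberate deviation from the literal hierarchy: genes not
planted as differentially expressed share one baseline mean across
conditions, so "non-DE" labels are exact nulls — otherwise every gene would
carry a random condition effect and benchmark labels would be meaningless.

Scenario sizes used by the test-suite studies (50 fitting seeds for
recovery, 20 seeds for cluster-number selection, 400-gene DE benchmarks,
$10^6$-draw moment checks) were chosen so each study's sampling error is
small relative to the property being asserted.

The generators do *not* emulate CEL-level artefacts — optical noise,
spatial gradients, cross-hybridisation, GC-content effects — nor the
empirical intensity distributions of any real benchmark set. Passing these
tests therefore establishes that the implementations are faithful to their
models and numerically sound, not that the models capture everything in
real array data. The multi-mapping tables here are synthetic; real analyses
require curated probe-to-transcript annotation.

## Known limitations

* Shape parameters recovered from few probes are weakly identified (the
  $\alpha$–$(c,d)$ ridge discussed above); uncertainty output should be
  taken seriously rather than the point estimates alone.
* Mean-field bias: the variational posteriors understate uncertainty
  somewhat, most visibly in the fitted between-replicate precision prior
  when measurement noise is large.
* The PPLR machinery scores one treatment–control contrast at a time;
  multi-way designs are combined but contrasted pairwise.
* MML selection compares models visited along the annihilation path; it
  does not exhaustively refit every $K$ with fresh multistarts (an option
  worth it only when clusters overlap heavily).
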