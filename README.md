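# uexpress

Uncertainty-propagating expression analysis for microarray probe data:
probe-level summarisation that reports a measurement error with every
expression value, and downstream methods — differential-expression scoring
and clustering — that consume that error instead of ignoring it.

The package is aimed at analysts working with Affymetrix-style probe
intensity data (exon arrays with multi-mapped probes, or PM-only 3'
GeneChip probe-sets) and, more generally, at anyone whose expression
estimates come with per-value standard deviations — the downstream methods
only need the *(mean, sd)* interchange format, whatever produced it.

## The models

**Summarisation.** Probe intensities follow a compound gamma: the intensity
is Ga(shape, rate) given a probe-specific rate ("probe effect"), and the
rate itself is Ga(c, d). Integrating the probe effect out gives the closed
form

p(y) = Γ(a+c) / (Γ(a)Γ(c)) · dᶜ y^(a−1) / (y+d)^(a+c),

and the marginal likelihood of a gene is one such factor per (probe,
array). For exon arrays a probe shared by several isoforms carries the
*sum* of their shapes α_kc (a sum of same-rate gammas is gamma in the
summed shape); for 3' probe-sets there is a single shape per array. MAP
fitting happens in log-parameter space; expression is then summarised by
the exact log-moments

E[log s] = ψ(α) − ψ(c) + log d,  Var[log s] = ψ′(α) + ψ′(c),

reported on the log2 scale as a Gaussian mean/sd per target and array.
Weak signal (small α) automatically gets a large sd.

**Differential expression.** Per gene, measured values x̂_ij with known
variances s²_ij sit above a latent true expression x_ij ~ N(μ_j, 1/λ),
condition means μ_j ~ N(μ0, 1/η0) and a gamma prior on the replicate
precision λ. The explicit latent layer makes every variational E-step
update analytic (no importance sampling); hyperparameters are estimated
across genes by empirical Bayes. The score is the probability of positive
log-ratio, PPLR = Φ((m_t − m_c)/√(v_t + v_c)); genes are ranked by
max(PPLR, 1 − PPLR), with direction from the sign of PPLR − 0.5. A
sampling-based reference implementation is included for validation.

**Clustering.** Replicated profiles are clustered with a Student's-t
mixture over latent condition-mean profiles, propagating the known
measurement variances and a per-gene replicate precision. Heavy tails make
the centres robust to outlying genes; the number of components is chosen
automatically by minimum message length with support-based component
annihilation.

**Synthetic data.** Seeded generators draw datasets from each of the three
models with recorded ground truth (planted DE signs, cluster memberships,
true parameters), so the whole pipeline is testable without any external
data.

## Worked example

```r
library(uexpress)

## isoform-level summarisation with uncertainty
sim <- simulate_gme(n_genes = 1, isoforms_per_gene = 2,
                    probes_per_gene = 8, n_arrays = 4, seed = 1)
er <- gme_summarize(sim$panel, sim$mapping, level = "transcript",
                    opts = gme_options(seed = 1))
round(er$mean, 2)
#>            a1    a2    a3    a4
#> g001_t1 -4.22 -3.54 -4.60 -1.13
#> g001_t2 -3.53 -1.16 -1.42 -2.39
round(er$sd, 2)
#>           a1   a2   a3   a4
#> g001_t1 0.85 0.68 0.96 0.36
#> g001_t2 0.68 0.37 0.39 0.49
```

Each cell is a log2 expression mean with its measurement error; note the
sds shrink where the fitted signal is strong (array `a4` of `g001_t1`).

```r
## differential expression from replicated measurements
simd <- simulate_ipplr(n_genes = 200, replicates = 3,
                       de_fraction = 0.2, effect_size = 1.5, seed = 1)
comb <- combine_replicates_ipplr(simd$er)   # analytic variational EM
de <- rank_de(pplr_score(comb, "cond2", "cond1"))
head(de, 5)
#>        gene    pplr direction prob_de rank
#> g0003 g0003 0.00143         -   0.999    1
#> g0160 g0160 0.99465         +   0.995    2
#> g0016 g0016 0.98296         +   0.983    3
#> g0007 g0007 0.01773         -   0.982    4
#> g0145 g0145 0.01913         -   0.981    5
```

`prob_de` near 1 is strong evidence either way; `direction` says which way
(`-` means down-regulated in the treatment). Against the planted truth this
ranking reaches a direction-aware AUC of 0.793 with only three replicates.

```r
## robust clustering with automatic choice of K
simc <- simulate_clusters(n_genes = 300,
                          centers = rbind(c(4, 12, 4), c(12, 4, 4), c(8, 8, 12)),
                          seed = 1)
res <- select_k_mml(simc$data, mincls = 1, maxcls = 8,
                    tmix_options(seed = 1, n_starts = 1))
res
#> cluster_result: selected K=3 (visited: 3, 2, 1)
evaluate_partition(res$membership, simc$truth$membership)
#> [1] 1
```

The message-length criterion recovers the three planted clusters exactly
(adjusted Rand index 1).

A command-line front end (`inst/cli/uexpress`) wraps the same functions:
`uexpress gme`, `uexpress pmmmgmos`, `uexpress ipplr`, `uexpress clustii`,
`uexpress normalize` and `uexpress simulate`, all operating on plain TSV
files (see the script header for flags).

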