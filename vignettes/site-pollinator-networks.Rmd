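---
title: "Site–pollinator networks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Site–pollinator networks: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pollinet)
options(pollinet.verbose = FALSE)
```

## The model

`pollinet` analyses weighted bipartite networks in which the two node
classes are *field sites* (lower level) and the *flower-visitor species*
recorded at them (higher level), with edge weights equal to total visits.
This inverts the usual plant–pollinator convention: because visitation is
recorded on a standardized sentinel plant at every site, a site node
summarizes habitat attributes rather than plant identity, and network
position becomes a property of places as well as of species. The pipeline
runs from raw visitation records to (i) node-level structure — the
specialization index d′, species strength, a modularity partition, and
Guimerà–Amaral roles — and (ii) regressions linking that structure to
sentinel-plant reproduction.

### Specialization d′

For a site $i$ with interaction frequencies $p_{ij} = A_{ij}/K_i$ and
partner availability $q_j = L_j/F$, the raw discrimination is the
Kullback–Leibler divergence $d_i = \sum_j p_{ij}\,\ln(p_{ij}/q_j)$ (nats).
It is standardized to $d' = (d - d_{\min})/(d_{\max} - d_{\min}) \in
[0,1]$, where the bounds are computed over integer reallocations of the
node's marginal total $K_i$:

* $d_{\max}$: the exact maximum over allocations with each partner capped
  at its observed total $L_j$. The objective is separable in the per-column
  allocation, so the maximum is found by a max-plus dynamic program over
  partners in $O(K_i \cdot F)$ — no heuristic. An exchange-type greedy
  ("fill the rarest partners first") is *not* used: concentrating the whole
  total on one moderately rare partner often beats spreading it across
  several rarest partners, so the greedy can understate $d_{\max}$ and even
  fall below the observed $d$. An unconstrained variant
  (`dmax_unconstrained`) that places all of $K_i$ on the single rarest
  partner is available for sensitivity analysis.
* $d_{\min}$: the divergence of the largest-remainder integer allocation
  proportional to $q$. In the continuous limit this is 0; at very small
  totals ($K_i \lesssim 4$ spread over several partners) the discrete
  allocation can exceed the observed divergence, in which case $d'$ floors
  at 0. This degenerate regime is documented rather than patched because
  the standardization formula is part of the index's definition.

A site whose visitors occur nowhere else attains $d' = 1$ exactly when its
partners' availability caps bind, which is the interpretable "fully
specialized site" case.

### Node strength

The dependency of site $i$ on species $j$ is $A_{ij}/K_i$; a species'
strength is the sum of its dependencies over sites. Species strengths sum
to the number of sites, which the tests assert as a conservation law.

### Modularity and its optimizer

Barber's weighted bipartite modularity is
$Q = \frac{1}{F}\sum_{ij}\left(A_{ij} - \frac{K_i L_j}{F}\right)
\delta(m_i, m_j)$, exactly 0 for the one-module partition and bounded in
$[-0.5, 1]$. The maximizing partition is searched by simulated annealing
over joint assignments (single-node reassignment to occupied or fresh
modules, plus whole-module merges; geometric cooling), followed by a
deterministic polishing loop that alternates (a) node sweeps to local
optimality, (b) best-pair module merges, and (c) randomized two-way module
splits refined by Kernighan–Lin-style passes. The split move matters: once
two planted modules collapse during the stochastic phase, node moves and
merges alone cannot separate them, and without it the returned Q
measurably trailed the planted partition's Q on synthetic landscapes. The
quantitative-bipartite-modules algorithm in the literature uses a
tree-based MCMC over the same objective; only the maximizing partition and
its Q enter any downstream quantity, and an exhaustive-enumeration oracle
over all set partitions of networks with up to 8 nodes (4140 partitions)
guards optimizer quality in the test suite.

Defaults: initial temperature 0.05 on the Q scale, cooling 0.995 per
sweep, 50 proposed moves per node per sweep, stop after 200 sweeps without
improvement (at most 1000), 3 independent restarts keeping the best
partition (ties: fewest modules). All are configurable through
`run_config(sa_params = ...)`. The returned partition carries both `Q`
(after polishing) and `Q_anneal` (the best-seen annealing value):
extending the sweep budget under a fixed seed extends the same
trajectory, so `Q_anneal` can only rise, and `Q >= Q_anneal` per run.
The polished `Q` itself is not guaranteed monotone across budgets — the
fewest-modules tie-break can hand different (equal-Q) states to the
polisher — which is why the guarantee is stated on `Q_anneal`.

### Null model and critical thresholds

`vaznull_one()` generates randomized networks preserving row totals,
column totals, the grand total, and the observed number of links. Links
are placed with probability proportional to $(K_i/F)(L_j/F)$, restricted
to cells covering a still-uncovered row or column until every row and
column has a link, then unconstrained; weights beyond the initial unit per
link are added one at a time under the marginal caps, with a bounded
weight-shift repair for the tail where row and column slack end up on
disjoint links. Every draw satisfies all four conservation laws exactly
(asserted on every draw in the tests). A fully constrained single-pass
rejection scheme was rejected: with realistic singleton species the
probability that an unconstrained sample covers every column is
vanishingly small, so it stalls on exactly the networks of interest.

The observed Q is converted to $z = (Q_{obs} - \bar{Q}_{null})/s_{null}$
with the sample standard deviation over `n_null` (default 100)
randomizations; $z > 2$ flags significant modularity. Critical role
thresholds are empirical quantiles (type 7) of the *pooled* null node
values per level — pooling across nodes matches the usage of the published
threshold code; a per-node variant is deliberately not implemented. "95%
confidence interval" is operationalized as the 0.975 quantile (upper limit
of a central 95% interval); the probability is exposed as
`threshold_quantile` rather than hidden. By default null searches use the
full annealing schedule; `fast_null = TRUE` quarters the budget and is
logged, because under-optimized null partitions bias the z-score upward.

### Node roles

The participation coefficient $c = 1 - \sum_t (k_{it}/k_i)^2$ and the
within-module degree $z = (k_{is} - \bar{k}_s)/s_s$ use interaction
*weights*, consistent with the weighted partition (a `binary` flag
recovers the classic presence–absence definitions, cross-checked in the
tests against a direct binary implementation). $z$ statistics are computed
over same-level nodes within the module — the standard choice for
bipartite roles; modules with a single same-level node or zero spread map
to $z = 0$ so classification is total. Roles use strict inequalities
against the thresholds (both exceeded: network hub; c only: connector; z
only: module hub; neither: peripheral).

### Linking structure to reproduction

Per plant, reproduction is standardized for flower availability:
`fert_prop = n_pods / (n_unfertilized_flowers + n_pods)`; seeds per pod
are pooled over pods. Site-level variances use the sample ($n-1$)
denominator, since with 15–18 plants per site they estimate sampling
variability. Four GLMs relate site means to network position:
fertilized-pod proportion ~ c and ~ d′ (quasi-binomial, logit) and seeds
per pod ~ c and ~ d′ (quasi-Poisson, log). The models are weighted **by
the per-site response variance** — mirroring the protocol this package
operationalizes, where site-mean responses are weighted with the variance
per site; the statistically conventional `inverse_variance` scheme is one
configuration flag away, and both directions are reported when they
disagree in sign. Wald tests use the t distribution on residual df with
Pearson-dispersion-scaled standard errors.

Land-use contrasts use the family appropriate to each response
(quasi-Poisson for richness/visits/seeds, quasi-binomial for proportions,
Gaussian for node metrics) with a dispersion-scaled F test. Pairwise
distance regressions use haversine distances (Earth radius 6371.0088 km)
against absolute metric differences; site pairs are *not* independent and
the simple-LM treatment is retained deliberately (no Mantel permutation) —
the non-independence note travels with the result object. "Similarity" is
reported on the dissimilarity (absolute difference) scale; a similarity
transform would flip slope signs, so the sign convention is stated in the
output rather than assumed.

Model selection over single-predictor Gaussian candidates uses
$AICc = AIC + 2k(k+1)/(n-k-1)$ with $k$ counting the variance parameter.
Models within ΔAICc < 2 of the best are flagged most explanatory, and if
the intercept-only model ranks first no candidate is considered suitable.

## The synthetic landscape generator

`generate_landscape()` emulates the study design the analysis assumes: 20
sites in four land uses (forest 6, avocado 5, dairy 4, potato 5), each
land use with a private species pool (planted modules) plus a shared
generalist pool; a `specialist_fraction` of private species are pinned to
a single site, and with probability `overlap` a private species ranges
landscape-wide (0 = perfect planted modules, 1 = fully mixed). Visit
counts are negative binomial (dispersion 1.5) rather than Poisson because
field visit counts are overdispersed — the very reason the GLMs are
quasi-likelihood. Reproduction is generated *causally downstream of the
realized network*: the fertilization probability is logistic in
standardized syrphid visits, hymenopteran visits and the site's realized
participation coefficient (computed by running the package's own
modularity and role code), and seeds per pod are Poisson with log-mean
linear in standardized total visits. Because c enters only through the
realized network, effect-recovery tests exercise the full pipeline rather
than an oracle shortcut. Predictors are z-scored inside the linear
predictor so effect magnitudes are comparable across configurations.

`paper_shaped_preset()` fixes the order composition to the strongly
Diptera-dominated ratios of the motivating system (Diptera ≫ Hymenoptera >
Lepidoptera > Coleoptera, with hoverflies near 48% of visits, ~57
expected visits per site) — a qualitative mimic: species identities,
abundance draws (Gamma weights with shape 0.7, giving realistic dominant
species) and coordinates (40 × 40 km box, ≥ 1 km site separation) are
synthetic. What passing recovery tests show is that *if* data have this
planted structure, the pipeline finds it; they cannot show that any
particular field dataset does.

Known departures from real field data: no spatial autocorrelation in
species distributions, no temporal structure across observation rounds
(counts are aggregated as the analysis aggregates them), and land-use
covariates beyond the categorical label are not generated.

## Numerical choices and problem sizes

* Annealing uses R's RNG throughout (reproducible under `set.seed()`);
  each stage derives an independent sub-seed from the global seed so toggling
  one stage leaves the others' streams untouched.
* Q comparisons use an absolute tolerance of 1e-12; the returned Q is
  recomputed exactly from the best assignment, not accumulated deltas.
* Degenerate inputs are defined, not errors: one-node levels give the
  single-module partition (warning), singleton modules give z = 0, zero
  variances get the smallest positive weight so no site is dropped
  silently.
* The test suite runs its stochastic checks at deliberately desk-scale
  sizes: optimizer-vs-enumeration on 50 networks of ≤ 8 nodes; d′ against
  the brute-force allocation oracle on 50 matrices with row totals ≤ 8;
  z-score calibration on 50 null-of-null replicates of an 8 × 10 network
  with 15 nulls each; planted-module recovery on 20 landscapes; effect
  sign recovery on 100 landscapes at |β_c| = 1. These sizes were chosen to
  give stable pass/fail behaviour at interactive runtimes.

## Limitations

* The annealing optimizer is a heuristic; its exactness is guaranteed only
  where enumeration certifies it (small networks). On field-scale networks
  the split-merge polishing makes it consistently at least as good as the
  planted partition in synthetic benchmarks, but global optimality is not
  certified.
* Null-derived thresholds inherit the Monte Carlo error of `n_null`;
  with 100 randomizations the 0.975 pooled quantile is stable to roughly
  ±0.02 on the c scale in the synthetic benchmarks.
* The distance–similarity regression deliberately reproduces the simple-LM
  treatment of non-independent pairs; its p-values should be read
  descriptively.
* Variance weighting (rather than inverse-variance) is faithful to the
  operationalized protocol but statistically unconventional; conclusions
  that flip between the two schemes should be treated as fragile — the
  package reports both signs when they disagree.
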