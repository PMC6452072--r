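# pollinet

Bipartite network analysis linking **pollinator communities to field
sites**, and network position to pollination function.

In mosaic agricultural landscapes, the question is not only *which*
insects visit flowers but *how the community is structured across
places*: do sites in different land uses draw on distinct visitor pools
(modules)? Which sites and species knit those modules together? And does
a site's position in that network predict how well plants reproduce
there? `pollinet` answers these questions for weighted site × species
visitation networks built from sentinel-plant surveys: sites are the
lower level, flower-visitor species the higher level, and edge weights
are total visits.

## What it computes

* **Specialization d′** per node: the Kullback–Leibler divergence of a
  node's interaction frequencies from partner availability,
  standardized to [0, 1] by exact integer-allocation bounds
  (`dprime()`). d′ = 1 marks a site whose visitors occur nowhere else.
* **Node strength**: the sum of partner dependencies `A_ij / K_i`
  (`node_strength()`); species strengths sum to the number of sites.
* **Barber weighted modularity** `Q = (1/F) Σ (A_ij − K_i L_j / F) δ(m_i, m_j)`
  maximized by simulated annealing with merge/split polishing
  (`barber_q()`, `optimize_modules()`), verified against exhaustive
  enumeration on small networks.
* **vaznull null models** preserving row totals, column totals, grand
  total and link count (`vaznull_one()`, `null_distributions()`), the
  modularity z-score, and null-derived critical thresholds for roles
  (`derive_thresholds()`).
* **Node roles**: participation coefficient c, within-module degree z,
  and the hub/connector/module-hub/peripheral classification
  (`node_roles()`).
* **Function regressions**: variance-weighted quasi-binomial /
  quasi-Poisson GLMs of plant reproduction on c and d′
  (`reproduction_models()`), land-use comparisons, pairwise
  distance–similarity regressions, and AICc model selection with the
  intercept-only guard (`aicc_selection()`).
* **A synthetic landscape generator** with planted modules and known
  effect sizes (`generate_landscape()`, `paper_shaped_preset()`), so
  every stage of the pipeline can be tested against ground truth.

## Worked example

Simulate a 20-site, 4-land-use landscape shaped like a tropical
sentinel-plant study (Diptera-dominated, ~48% hoverfly visits), then run
the full analysis:

```r
library(pollinet)
sim <- tempfile()
cmd_simulate(sim, paper_shaped_preset(seed = 1))
cfg <- run_config(random_seed = 1, n_null = 20, fast_null = TRUE)
res <- cmd_analyze(file.path(sim, "visitation.csv"),
                   file.path(sim, "plants.csv"), "out", cfg)
print(res)
#> pollinet pipeline result
#>   20 sites x 51 species, 1139 total visits
#>   Q = 0.298 (6 modules), z = 11.52 vs 20 nulls *
#>   thresholds: sites c > 0.79, z > 1.49; species c > 0.80, z > 2.47
#>   strongest species: shared_sp01 (strength 4.19)
res$reproduction$directions
#>         response predictor      slope sign          p
#> 1 mean_fert_prop         c 11.9096739    1 0.01002236
#> 2 mean_fert_prop   d_prime -3.6211352   -1 0.28301588
#> 3     mean_seeds         c  0.8626946    1 0.30449381
#> 4     mean_seeds   d_prime  0.3861271    1 0.58580923
```

Reading the output: the landscape network splits into 6 modules with
modularity Q = 0.30, far above its vaznull randomizations (z = 11.5 > 2,
so the planted land-use pools are detected as significant structure).
The thresholds line gives the null-derived critical values of the
participation coefficient and within-module degree that a site (or
species) must exceed to count as a connector or hub. The strongest
species is the one the sites collectively depend on most. The
reproduction table shows the planted positive effect of a site's
participation coefficient recovered with the expected sign (slope > 0,
p = 0.01 for fertilized pods) under the variance-weighted quasi-GLMs.

All artifacts (`node_metrics.csv`, `partition.csv`, `null_summary.csv`,
`models.csv`, `aicc.csv`, `run_summary.json`) are written to the output
directory; a shell entry point with the same two subcommands is in
`exec/pollinet`.

See `vignettes/site-pollinator-networks.Rmd` for the model, the
estimators, the generator's assumptions, and the package's numerical
choices.

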