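# sociodep

Social-unit structure and heterogeneity of fisheries depredation from
photo-identification data.

Some toothed-whale populations feed on fish caught on longline gear
("depredation"). Within such a population, stable social units — groups
of individuals with strong long-term associations — may exploit this
feeding opportunity to very different extents, which changes both their
exposure to retaliation and the food subsidy they receive. `sociodep`
implements the complete analysis chain a behavioural ecologist needs to
quantify that heterogeneity from photo-identification records collected
around fishing vessels and from shore:

1. **Sightings** — build sightings from photo logs (shore photos chained
   at < 1 h gaps within a bay; one sighting per longline haul at sea) and
   apply the standard bias filters (individual tenure, minimum
   photographic effort per sighting).
2. **Association network** — Simple Ratio Index
   `SRI = x / (x + yAB + yA + yB)` per dyad; day-constrained data-stream
   permutation tests for preferred/avoided association (checkerboard
   swaps preserving group sizes and daily individual records, exact
   serial Monte Carlo p-values); Mantel comparison of shore- vs
   vessel-based associations; maximum-likelihood social differentiation
   `S` (CV of the latent association indices under a beta-binomial
   model) with the `S^2 H` power heuristic.
3. **Social units** — Leiden optimisation of the weighted Constant Potts
   Model, `sum_c (w_c_int - gamma * n_c (n_c - 1) / 2)`, with multi-start
   stability and a resolution (gamma) scan.
4. **Spatial range** — per-unit minimum convex polygons, 0.1-degree
   graticule-cell occupancy and Gaussian-kernel utilisation
   distributions (UD50/UD95) of depredation-event locations, as
   percentages of the pooled "fishing area", with annual series and
   cumulative expansion curves.
5. **Occurrence model** — binomial GLMM (logit link) of unit presence at
   depredation events with year, month and unit as categorical fixed
   terms and photographic effort as a random intercept; 12-h
   same-vessel exclusion; forward AICc selection; simulated
   scaled-residual diagnostics; estimated marginal means per unit with
   Holm-adjusted pairwise contrasts.
6. **Synthetic data** — a generator with known ground truth (planted
   units, occurrence probabilities, spatial ranges, effort-driven
   detection) so every stage is testable by parameter recovery.

## Worked example

```r
library(sociodep)

sim <- simulate_dataset(sim_config(), seed = 42)   # study-scale synthetic data
ds  <- sim$dataset
ds
#> kw_dataset: 1376 sightings (140 shore, 1236 vessel), 79 individuals

rds <- restrict_dataset(ds, min_years = 6, min_last_year = 2019,
                        min_photos_per_sighting = 42)
am  <- compute_sri(rds, "sighting")
am
#> sri_matrix: 79 individuals, sampling period = sighting
#>   mean SRI 0.101, nonzero dyads 3018/3081

p <- detect_units(am, gamma = 0.28, n_restarts = 10, seed = 3)
p
#> unit_partition: 17 units (sizes 8,8,7,6,6,6,5,5,5,4,4,4,3,3,2,2,1) at gamma = 0.28
#>   CPM quality 121.979, stability 1.000 over 10 restarts

mclust::adjustedRandIndex(sim$truth$membership[names(p$membership)],
                          p$membership)
#> [1] 1
```

The detected partition recovers the planted 17 social units exactly
(adjusted Rand index 1), at the same resolution and population size as
the real study system. From here, `range_proportions(rds, p)` summarises
each unit's share of the fishing area, and

```r
rec <- occurrence_records(rds, p, dedup_hours = 12)
fit <- fit_glmm(rec, c("year", "month", "unit"), "effort")
fit
#> Binomial mixed model: present ~ year + month + unit + (1 | effort)
#>   LL = -7381.79, K = 46, AICc = 14855.80, R2m = 10.13%, R2c = 10.13%
emmeans_units(fit)$probabilities   # per-unit marginal probabilities + 95% CI
```

gives each unit's relative probability of presence at a depredation
event; the planted probabilities span 4--22.5% and the estimates rank
them with Spearman correlation 0.98 in this run.

See `vignettes/methods.Rmd` for the models, their assumptions, and
every numerical convention.

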